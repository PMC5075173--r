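# Registry of published pKa parameter sets for the nine ionizable groups of
# a polypeptide: the free N- and C-termini plus the side chains of
# Cys, Asp, Glu, His, Lys, Arg and Tyr.

# canonical group order used everywhere in the package
PKA_GROUPS <- c("NTERM", "CTERM", "C", "D", "E", "H", "K", "R", "Y")

# groups ionizing negatively (deprotonated above pKa) vs positively
PKA_NEG_GROUPS <- c("CTERM", "C", "D", "E", "Y")
PKA_POS_GROUPS <- c("NTERM", "H", "K", "R")

new_pka_set <- function(values, name, provenance = "", simplified = FALSE) {
  stopifnot(is.numeric(values), length(values) == 9L)
  names(values) <- PKA_GROUPS
  structure(
    list(name = name, values = values, provenance = provenance,
         simplified = simplified),
    class = "pka_set"
  )
}

#' @export
print.pka_set <- function(x, ...) {
  cat(sprintf("<pka_set> %s%s\n", x$name,
              if (isTRUE(x$simplified)) " [simplified]" else ""))
  print(round(x$values, 4))
  if (nzchar(x$provenance)) cat("note:", x$provenance, "\n")
  invisible(x)
}

# Built-in registry. Order NTERM, CTERM, C, D, E, H, K, R, Y.
# NA marks a group the original model does not ionize at all (its charge
# contribution is zero); only the six-parameter Patrickios model has those.
.pka_builtin <- local({
  row <- function(...) c(...)
  tbl <- list(
    EMBOSS     = row(8.6,   3.6,   8.5,   3.9,   4.1,   6.5,   10.8,   12.5,   10.1),
    DTASelect  = row(8.0,   3.1,   8.5,   4.4,   4.4,   6.5,   10.0,   12.0,   10.0),
    Solomons   = row(9.6,   2.4,   8.3,   3.9,   4.3,   6.0,   10.5,   12.5,   10.1),
    Sillero    = row(8.2,   3.2,   9.0,   4.0,   4.5,   6.4,   10.4,   12.0,   10.0),
    Rodwell    = row(8.0,   3.1,   8.33,  3.68,  4.25,  6.0,   11.5,   11.5,   10.07),
    Patrickios = row(11.2,  4.2,   NA,    4.2,   4.2,   NA,    11.2,   11.2,   NA),
    Wikipedia  = row(8.2,   3.65,  8.18,  3.9,   4.07,  6.04,  10.54,  12.48,  10.46),
    Lehninger  = row(9.69,  2.34,  8.33,  3.86,  4.25,  6.0,   10.5,   12.4,   10.0),
    Grimsley   = row(7.7,   3.3,   6.8,   3.5,   4.2,   6.6,   10.5,   12.04,  10.3),
    Toseland   = row(8.71,  3.19,  6.87,  3.6,   4.29,  6.33,  10.45,  12.0,   9.61),
    Thurlkill  = row(8.0,   3.67,  8.55,  3.67,  4.25,  6.54,  10.4,   12.0,   9.84),
    Nozaki     = row(7.5,   3.8,   9.5,   4.0,   4.4,   6.3,   10.4,   12.0,   9.6),
    Dawson     = row(8.2,   3.2,   8.3,   3.9,   4.3,   6.0,   10.5,   12.0,   10.1),
    Bjellqvist = row(7.5,   3.55,  9.0,   4.05,  4.45,  5.98,  10.0,   12.0,   10.0),
    ProMoST    = row(7.26,  3.57,  8.28,  4.07,  4.45,  6.08,  9.8,    12.5,   9.84),
    IPC_protein = row(9.094, 2.869, 7.555, 3.872, 4.412, 5.637, 9.052, 11.84,  10.85),
    IPC_peptide = row(9.564, 2.383, 8.297, 3.887, 4.317, 6.018, 10.517, 12.503, 10.071)
  )
  notes <- c(
    Patrickios = paste("six-parameter model: Cys, His and Tyr do not ionize;",
                       "excluded from consensus panels"),
    Grimsley = "Arg pKa 12.04 imputed (average over other sets; Arg not measured)",
    Dawson = "terminal pKa values 8.2/3.2 imputed from the Sillero set",
    Wikipedia = "community-compiled values, no primary literature reference",
    Bjellqvist = "nine-parameter reduction; positional terminal-residue pKa values not modeled",
    ProMoST = "nine-parameter reduction of the 72-parameter positional model",
    IPC_protein = "computationally optimized against protein 2D-PAGE pI data",
    IPC_peptide = "computationally optimized against peptide isoelectric-focusing pI data"
  )
  out <- lapply(names(tbl), function(nm) {
    new_pka_set(tbl[[nm]], name = nm,
                provenance = if (nm %in% names(notes)) notes[[nm]] else "",
                simplified = identical(nm, "Patrickios"))
  })
  names(out) <- names(tbl)
  out
})

#' List the built-in pKa sets
#'
#' @return Character vector of the 17 registered set labels, in fixed
#'   registry order.
#' @export
#' @examples
#' list_pka_sets()
list_pka_sets <- function() names(.pka_builtin)

#' Retrieve a built-in pKa set
#'
#' Looks up one of the built-in pKa parameter sets by name
#' (case-insensitively). Each set carries nine acid dissociation constants:
#' the free N- and C-termini and the side chains of C, D, E, H, K, R and Y.
#'
#' @param name Label of a registered set, e.g. `"EMBOSS"` or `"IPC_peptide"`.
#'   Case-insensitive.
#' @return A `pka_set` object: list with elements `name`, `values` (named
#'   numeric of length 9, names `NTERM, CTERM, C, D, E, H, K, R, Y`; `NA`
#'   marks a group the model treats as non-ionizing), `provenance` and
#'   `simplified`.
#' @export
#' @examples
#' get_pka_set("EMBOSS")$values[["C"]]   # 8.5
#' get_pka_set("ipc_peptide")$values[["NTERM"]]
get_pka_set <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  hit <- match(tolower(name), tolower(names(.pka_builtin)))
  if (is.na(hit)) {
    stop(sprintf("unknown pKa set '%s'; available sets: %s",
                 name, paste(names(.pka_builtin), collapse = ", ")),
         call. = FALSE)
  }
  .pka_builtin[[hit]]
}

#' Assemble a pKa set from raw values
#'
#' @param values Named numeric vector with entries for all nine groups
#'   `NTERM, CTERM, C, D, E, H, K, R, Y` (any order). Each value must lie in
#'   the open interval (0, 14); `NA` declares the group non-ionizing.
#' @param name Label for the new set.
#' @param provenance Optional free-text note.
#' @param simplified Logical; flags sets that should be excluded from
#'   consensus panels (e.g. models with missing groups).
#' @return A `pka_set`.
#' @export
pka_set <- function(values, name = "custom", provenance = "",
                    simplified = FALSE) {
  if (is.null(names(values)) || !all(PKA_GROUPS %in% names(values))) {
    missing <- setdiff(PKA_GROUPS, names(values))
    stop("pKa values missing for group(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  v <- as.numeric(values[PKA_GROUPS])
  bad <- !is.na(v) & (!is.finite(v) | v <= 0 | v >= 14)
  if (any(bad)) {
    stop("pKa value out of range (0, 14) for group(s): ",
         paste(PKA_GROUPS[bad], collapse = ", "), call. = FALSE)
  }
  new_pka_set(v, name = name, provenance = provenance,
              simplified = simplified)
}

#' Read a pKa set from a config file
#'
#' The config format is flat key-value text: one line per group,
#' `GROUP<TAB>value` (whitespace-separated also accepted), groups named
#' `NTERM, CTERM, C, D, E, H, K, R, Y`. Lines starting with `#` are ignored.
#' The literal token `NA` declares a non-ionizing group.
#'
#' @param path Path to the config file.
#' @param name Label for the loaded set; defaults to the file's base name.
#' @return A `pka_set`. The set is not added to the built-in registry.
#' @export
load_pka_set <- function(path, name = NULL) {
  if (!file.exists(path)) stop("pKa config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  toks <- strsplit(lines, "[\t ]+")
  keys <- toupper(vapply(toks, `[`, "", 1L))
  vals <- suppressWarnings(as.numeric(vapply(toks, `[`, "", 2L)))
  raw <- vapply(toks, `[`, "", 2L)
  bad_num <- is.na(vals) & toupper(raw) != "NA"
  if (any(bad_num)) {
    stop("unparseable pKa value for group(s): ",
         paste(keys[bad_num], collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(keys, PKA_GROUPS)
  if (length(unknown)) {
    warning("ignoring unknown group(s) in pKa config: ",
            paste(unknown, collapse = ", "))
  }
  v <- vals[match(PKA_GROUPS, keys)]
  absent <- !(PKA_GROUPS %in% keys)
  if (any(absent)) {
    stop("pKa config missing group(s): ",
         paste(PKA_GROUPS[absent], collapse = ", "), call. = FALSE)
  }
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  pka_set(stats::setNames(v, PKA_GROUPS), name = name,
          provenance = paste("loaded from", basename(path)))
}

#' Write a pKa set to a config file
#'
#' Inverse of [load_pka_set()]. Values are written with enough digits to
#' round-trip bit-exactly.
#'
#' @param pka A `pka_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pka_set <- function(pka, path) {
  stopifnot(inherits(pka, "pka_set"))
  vals <- vapply(pka$values, function(x) {
    if (is.na(x)) "NA" else format(x, digits = 17, scientific = FALSE)
  }, "")
  writeLines(c(sprintf("# pKa set: %s", pka$name),
               paste(PKA_GROUPS, vals, sep = "\t")),
             path)
  invisible(path)
}

# resolve a user argument that may be a label, a pka_set, or a list of either
as_pka_set <- function(x) {
  if (inherits(x, "pka_set")) return(x)
  if (is.character(x) && length(x) == 1L) return(get_pka_set(x))
  stop("expected a pka_set or a set label", call. = FALSE)
}

as_pka_panel <- function(x) {
  if (inherits(x, "pka_set")) return(stats::setNames(list(x), x$name))
  if (is.list(x)) {
    out <- lapply(x, as_pka_set)
    names(out) <- vapply(out, `[[`, "", "name")
    return(out)
  }
  if (is.character(x)) {
    out <- lapply(x, get_pka_set)
    names(out) <- vapply(out, `[[`, "", "name")
    return(out)
  }
  stop("expected pka_set objects or set labels", call. = FALSE)
}

#' Default consensus panel of literature pKa sets
#'
#' The per-record consensus pI ("Avg_pI") is defined as the mean prediction
#' over the literature sets, excluding the simplified Patrickios model and
#' the two computationally optimized IPC sets, so that no optimized method
#' is favored by the consensus it is compared to.
#'
#' @return Character vector of 14 set labels.
#' @export
default_consensus_panel <- function() {
  setdiff(list_pka_sets(), c("Patrickios", "IPC_protein", "IPC_peptide"))
}
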
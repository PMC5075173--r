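# Henderson-Hasselbalch net-charge model and bisection pI solver.
#
# The net charge of a polypeptide at a given pH is the sum over its
# ionizable groups of logistic terms:
#   negative groups (C-terminus, C, D, E, Y):  -1 / (1 + 10^(pKa - pH))
#   positive groups (N-terminus, H, K, R):      1 / (1 + 10^(pH - pKa))
# The charge is strictly decreasing in pH, so the isoelectric point (the
# unique pH of zero net charge) can be found by bisection.

AA_STANDARD <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# characters tolerated in input but carrying no charge model: ambiguity
# codes, rare residues, stops and gaps. U (selenocysteine) is deliberately
# NOT mapped onto C: the model enumerates exactly seven side chains.
AA_TOLERATED <- c("B", "Z", "J", "X", "U", "O", "*", "-", ".")

IONIZABLE_LETTERS <- c("C", "D", "E", "H", "K", "R", "Y")

# strip whitespace, upper-case, and drop characters outside the 20-letter
# alphabet (one aggregated warning). Returns a character vector of residues.
clean_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- gsub("[[:space:]]", "", sequence)
  if (!nzchar(s)) stop("empty sequence", call. = FALSE)
  chars <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  keep <- chars %in% AA_STANDARD
  if (!all(keep)) {
    skipped <- chars[!keep]
    unknown <- setdiff(skipped, AA_TOLERATED)
    warning(sprintf("skipping %d non-standard character(s): %s",
                    length(skipped),
                    paste(unique(skipped), collapse = " ")),
            call. = FALSE)
    if (length(unknown) == length(skipped) && !any(keep)) {
      stop("sequence contains no standard amino-acid letters", call. = FALSE)
    }
  }
  chars[keep]
}

#' Count the ionizable groups of a sequence
#'
#' Tallies the seven charged residues (C, D, E, H, K, R, Y) and records
#' whether the free N- and C-termini are present. Non-standard letters
#' (ambiguity codes, `U`, `O`, `*`, gaps) carry no charge and are skipped
#' with a warning; selenocysteine is not treated as cysteine.
#'
#' @param sequence Amino-acid string (case-insensitive; whitespace ignored).
#' @param nterm,cterm Logical; set to `FALSE` for chemically blocked termini.
#' @return An `ionizable_counts` object: list with `counts` (named integer,
#'   one entry per ionizable letter), `has_nterm`, `has_cterm` and `length`
#'   (number of standard residues counted).
#' @export
#' @examples
#' count_ionizable("DECK")$counts
count_ionizable <- function(sequence, nterm = TRUE, cterm = TRUE) {
  chars <- clean_sequence(sequence)
  counts <- vapply(IONIZABLE_LETTERS, function(a) sum(chars == a), 0L)
  structure(
    list(counts = counts, has_nterm = isTRUE(nterm),
         has_cterm = isTRUE(cterm), length = length(chars)),
    class = "ionizable_counts"
  )
}

#' @export
print.ionizable_counts <- function(x, ...) {
  cat("<ionizable_counts>", x$length, "residues;",
      "N-term:", x$has_nterm, "C-term:", x$has_cterm, "\n")
  print(x$counts)
  invisible(x)
}

# counts object -> length-9 group multiplicity vector in PKA_GROUPS order
group_vector <- function(counts) {
  c(NTERM = as.numeric(counts$has_nterm),
    CTERM = as.numeric(counts$has_cterm),
    counts$counts[c("C", "D", "E")],
    counts$counts["H"], counts$counts["K"], counts$counts["R"],
    counts$counts["Y"])[PKA_GROUPS]
}

# n x 9 group multiplicity matrix for a character vector of sequences
count_matrix <- function(sequences, nterm = TRUE, cterm = TRUE) {
  m <- t(vapply(sequences,
                function(s) group_vector(count_ionizable(s, nterm, cterm)),
                numeric(9L)))
  dimnames(m) <- list(NULL, PKA_GROUPS)
  m
}

# vectorized net charge: m is an n x 9 multiplicity matrix, ph a length-n
# (or length-1) vector, pka a pka_set. NA pKa entries contribute nothing.
charge_matrix <- function(m, ph, pka) {
  v <- pka$values
  z <- numeric(nrow(m))
  for (g in PKA_NEG_GROUPS) {
    if (!is.na(v[[g]])) z <- z - m[, g] / (1 + 10^(v[[g]] - ph))
  }
  for (g in PKA_POS_GROUPS) {
    if (!is.na(v[[g]])) z <- z + m[, g] / (1 + 10^(ph - v[[g]]))
  }
  z
}

#' Net charge of a polypeptide at a given pH
#'
#' Sums the Henderson-Hasselbalch charge of every ionizable group: negative
#' groups contribute \eqn{-1/(1+10^{pK_a-pH})}, positive groups
#' \eqn{1/(1+10^{pH-pK_a})}. Strictly decreasing in pH.
#'
#' @param x An amino-acid string or an `ionizable_counts` object.
#' @param ph Numeric vector of pH values.
#' @param pka A `pka_set` or set label (see [get_pka_set()]).
#' @return Numeric vector of net charges (elementary-charge units), one per
#'   element of `ph`.
#' @export
#' @examples
#' net_charge("GGGG", 7, "EMBOSS")
net_charge <- function(x, ph, pka) {
  stopifnot(is.numeric(ph), all(is.finite(ph)))
  pka <- as_pka_set(pka)
  counts <- if (inherits(x, "ionizable_counts")) x else count_ionizable(x)
  m <- matrix(group_vector(counts), nrow = 1L,
              dimnames = list(NULL, PKA_GROUPS))
  vapply(ph, function(p) charge_matrix(m, p, pka), 0)
}

# Vectorized bisection on [0, 14]. One initial sign test at `start` (the
# warm start, default 6.68 = the SwissProt-wide average pI) selects the
# sub-bracket; regular halving follows until the bracket width is <=
# precision. Returns the bracket midpoints. Rows whose charge has constant
# sign on [0, 14] get NA (possible only for pathological custom sets or
# when requested via `check_root`).
solve_pi_matrix <- function(m, pka, precision = 0.001, start = 6.68,
                            check_root = TRUE) {
  n <- nrow(m)
  if (n == 0L) return(numeric(0))
  lo <- rep(0, n)
  hi <- rep(14, n)
  ok <- rep(TRUE, n)
  if (check_root) {
    ok <- charge_matrix(m, 0, pka) > 0 & charge_matrix(m, 14, pka) < 0
  }
  ch <- charge_matrix(m, start, pka)
  lo <- ifelse(ch > 0, start, lo)
  hi <- ifelse(ch > 0, hi, start)
  it <- 0L
  while (max(hi - lo) > precision) {
    mid <- (lo + hi) / 2
    ch <- charge_matrix(m, mid, pka)
    up <- ch > 0
    lo <- ifelse(up, mid, lo)
    hi <- ifelse(up, hi, mid)
    it <- it + 1L
  }
  pi <- (lo + hi) / 2
  pi[!ok] <- NA_real_
  attr(pi, "iterations") <- it
  pi
}

#' Isoelectric point of a sequence by bisection
#'
#' Solves `net_charge(x, pH, pka) == 0` for pH on the bracket \[0, 14\].
#' The search starts with one sign test at `start` (default 6.68, the
#' average pI over the SwissProt database) that selects the sub-bracket,
#' then halves the bracket until its width is at most `precision` and
#' reports the midpoint; convergence takes about a dozen iterations at the
#' default 0.001 precision.
#'
#' @param x Amino-acid string or `ionizable_counts`.
#' @param pka A `pka_set` or set label.
#' @param precision Bracket width at convergence, in pH units.
#' @param start Warm-start pH for the initial sign test.
#' @return A `pi_prediction`: list with `pi`, `pka_set`, `iterations` and
#'   `precision`.
#' @export
#' @examples
#' isoelectric_point("GGGG", "IPC_peptide")$pi   # midpoint of the termini pKa
isoelectric_point <- function(x, pka, precision = 0.001, start = 6.68) {
  stopifnot(is.numeric(precision), precision > 0,
            is.numeric(start), start > 0, start < 14)
  pka <- as_pka_set(pka)
  counts <- if (inherits(x, "ionizable_counts")) x else count_ionizable(x)
  gv <- group_vector(counts)
  active <- !is.na(pka$values) & gv > 0
  if (!any(active)) {
    stop("sequence has no ionizable groups under pKa set '", pka$name,
         "'; the net charge is identically zero", call. = FALSE)
  }
  m <- matrix(gv, nrow = 1L, dimnames = list(NULL, PKA_GROUPS))
  pi <- solve_pi_matrix(m, pka, precision = precision, start = start)
  if (is.na(pi[1])) {
    stop("net charge has constant sign on [0, 14] under pKa set '",
         pka$name, "'; no isoelectric point in range", call. = FALSE)
  }
  structure(
    list(pi = as.numeric(pi[1]), pka_set = pka$name,
         iterations = attr(pi, "iterations"), precision = precision),
    class = "pi_prediction"
  )
}

#' @export
print.pi_prediction <- function(x, ...) {
  cat(sprintf("pI = %.3f (pKa set %s, %d bisection iterations)\n",
              x$pi, x$pka_set, x$iterations))
  invisible(x)
}

# average residue masses (Da); free polypeptide = sum + one water
AA_AVG_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_AVG_MASS <- 18.01524

#' Average molecular weight of a polypeptide
#'
#' Sum of average (not monoisotopic) residue masses plus one water.
#' Non-standard letters are skipped with a warning.
#'
#' @param sequence Amino-acid string.
#' @return Mass in Daltons.
#' @export
#' @examples
#' molecular_weight("G")   # 75.07, free glycine
molecular_weight <- function(sequence) {
  chars <- clean_sequence(sequence)
  sum(AA_AVG_MASS[chars]) + WATER_AVG_MASS
}

#' Amino-acid composition
#'
#' @param sequence Amino-acid string.
#' @return Named numeric vector of residue fractions (letters present in the
#'   sequence only); sums to 1.
#' @export
aa_composition <- function(sequence) {
  chars <- clean_sequence(sequence)
  tab <- table(chars)
  out <- as.numeric(tab) / length(chars)
  names(out) <- names(tab)
  out
}
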
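# pI-annotated FASTA I/O and the dataset curation pipeline:
# merge replicates & average pI -> remove annotation-error outliers
# (squared deviation from the consensus prediction above a threshold)
# -> cluster near-identical sequences -> train/test split.

#' Construct a pI-annotated sequence dataset
#'
#' @param id Character vector of record identifiers.
#' @param sequence Character vector of amino-acid sequences.
#' @param pis List of numeric vectors: the experimental pI measurements of
#'   each record (possibly empty). A plain numeric vector is accepted for
#'   one-measurement-per-record data.
#' @param source Optional character vector of free-text source tags.
#' @return A `pi_dataset`: data frame with columns `id`, `sequence`, `pis`
#'   (list column), `consensus_pi` (NA until [merge_and_average()] runs) and
#'   `source`.
#' @export
pi_dataset <- function(id, sequence, pis = vector("list", length(id)),
                       source = "") {
  if (is.numeric(pis)) pis <- as.list(pis)
  stopifnot(length(id) == length(sequence), length(pis) == length(id))
  pis <- lapply(pis, as.numeric)
  bad <- vapply(pis, function(p) any(!is.finite(p) | p <= 0 | p >= 14), TRUE)
  if (any(bad)) {
    stop("experimental pI values must lie in (0, 14); offending record(s): ",
         paste(utils::head(id[bad], 5L), collapse = ", "), call. = FALSE)
  }
  d <- data.frame(id = as.character(id), sequence = as.character(sequence),
                  consensus_pi = NA_real_,
                  source = rep_len(as.character(source), length(id)),
                  stringsAsFactors = FALSE)
  d$pis <- pis
  d <- d[, c("id", "sequence", "pis", "consensus_pi", "source")]
  class(d) <- c("pi_dataset", "data.frame")
  d
}

#' @export
print.pi_dataset <- function(x, ...) {
  cat(sprintf("<pi_dataset> %d record(s); %d with consensus pI\n",
              nrow(x), sum(!is.na(x$consensus_pi))))
  if (nrow(x)) {
    show <- utils::head(x, 6L)
    cat(paste(sprintf(
      "  %s  [%s]  pI: %s%s", show$id,
      ifelse(nchar(show$sequence) > 18,
             paste0(substr(show$sequence, 1, 15), "..."), show$sequence),
      vapply(show$pis, function(p)
        if (length(p)) paste(round(p, 3), collapse = ",") else "-", ""),
      ifelse(is.na(show$consensus_pi), "",
             sprintf("  consensus %.3f", show$consensus_pi))),
      collapse = "\n"), "\n")
    if (nrow(x) > 6L) cat("  ...\n")
  }
  invisible(x)
}

# extract pI measurements from one FASTA header of the annotated dialect:
#   >id|[5.17, 5.27]                      (canonical)
#   >P04807-1|['5.17/55102', '5.27/54793']  (legacy pI/mass tokens)
# Returns list(id=, pis=, parseable=).
parse_pi_header <- function(header) {
  header <- trimws(header)
  bar <- regexpr("|", header, fixed = TRUE)
  if (bar < 0) return(list(id = header, pis = numeric(0), parseable = TRUE))
  id <- substr(header, 1L, bar - 1L)
  rest <- substr(header, bar + 1L, nchar(header))
  br <- regmatches(rest, regexpr("\\[[^]]*\\]", rest))
  if (!length(br)) return(list(id = id, pis = numeric(0), parseable = FALSE))
  inner <- substr(br, 2L, nchar(br) - 1L)
  toks <- strsplit(inner, ",", fixed = TRUE)[[1]]
  # strip any quoting character (ASCII or typographic) and whitespace
  toks <- gsub("[\"'′‘’[:space:]]", "", toks)
  toks <- toks[nzchar(toks)]
  if (!length(toks)) return(list(id = id, pis = numeric(0), parseable = FALSE))
  pi_part <- sub("/.*$", "", toks)
  vals <- suppressWarnings(as.numeric(pi_part))
  if (any(is.na(vals))) return(list(id = id, pis = numeric(0), parseable = FALSE))
  list(id = id, pis = vals, parseable = TRUE)
}

#' Read a (pI-annotated) FASTA file
#'
#' Reads standard FASTA; headers of the form `>id|[5.17, 5.27]` or the
#' legacy `>id|['5.17/55102', '5.27/54793']` (pI/molecular-weight tokens)
#' additionally carry experimental pI measurements. Headers with an
#' annotation block that cannot be parsed yield records with no measurements
#' and one aggregated warning.
#'
#' @param path FASTA file path.
#' @param source Source tag stored on every record; defaults to the file
#'   base name.
#' @return A [pi_dataset()].
#' @export
read_pi_fasta <- function(path, source = basename(path)) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (!length(set)) return(pi_dataset(character(0), character(0), source = source))
  parsed <- lapply(names(set), parse_pi_header)
  n_bad <- sum(!vapply(parsed, `[[`, TRUE, "parseable"))
  if (n_bad > 0) {
    warning(sprintf("%d header(s) with unparseable pI annotation in %s",
                    n_bad, path), call. = FALSE)
  }
  pi_dataset(id = vapply(parsed, `[[`, "", "id"),
             sequence = as.character(set),
             pis = lapply(parsed, `[[`, "pis"),
             source = source)
}

#' Write a pI-annotated FASTA file
#'
#' Canonical writer for the dialect read by [read_pi_fasta()]: records with
#' measurements get headers `>id|[pi1, pi2, ...]`, records without get
#' plain `>id`.
#'
#' @param records A `pi_dataset`.
#' @param path Output path.
#' @param width Line width for the sequence block.
#' @return `path`, invisibly.
#' @export
write_pi_fasta <- function(records, path, width = 80L) {
  stopifnot(inherits(records, "pi_dataset"))
  headers <- vapply(seq_len(nrow(records)), function(i) {
    p <- records$pis[[i]]
    if (length(p)) {
      sprintf("%s|[%s]", records$id[i],
              paste(format(p, digits = 15, trim = TRUE), collapse = ", "))
    } else records$id[i]
  }, "")
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Merge replicate records and average their pI measurements
#'
#' Records with no usable pI measurement are dropped (their number is
#' messaged). Records with byte-identical sequences are merged into one,
#' pooling all measurements; each surviving record gets
#' `consensus_pi = mean(pooled measurements)`.
#'
#' @param records A `pi_dataset`.
#' @return A `pi_dataset` with one record per unique sequence and
#'   `consensus_pi` filled. Attribute `n_dropped_no_pi` carries the number
#'   of measurement-free records dropped.
#' @export
merge_and_average <- function(records) {
  stopifnot(inherits(records, "pi_dataset"))
  has_pi <- vapply(records$pis, length, 0L) > 0L
  n_drop <- sum(!has_pi)
  if (n_drop > 0) {
    message(n_drop, " record(s) without pI measurements dropped")
  }
  r <- records[has_pi, , drop = FALSE]
  if (!nrow(r)) {
    out <- pi_dataset(character(0), character(0))
    attr(out, "n_dropped_no_pi") <- n_drop
    return(out)
  }
  grp <- match(r$sequence, unique(r$sequence))
  idx <- split(seq_len(nrow(r)), grp)
  ids <- vapply(idx, function(i) r$id[i[1]], "")
  seqs <- vapply(idx, function(i) r$sequence[i[1]], "")
  pooled <- lapply(idx, function(i) unlist(r$pis[i], use.names = FALSE))
  src <- vapply(idx, function(i)
    paste(unique(r$source[i]), collapse = "+"), "")
  out <- pi_dataset(ids, seqs, pooled, source = src)
  out$consensus_pi <- vapply(pooled, mean, 0)
  attr(out, "n_dropped_no_pi") <- n_drop
  attr(out, "n_merged") <- nrow(r) - nrow(out)
  out
}

# mean predicted pI per record over a panel of pKa sets
panel_mean_pi <- function(records, panel, precision = 0.001) {
  panel <- as_pka_panel(panel)
  m <- count_matrix(records$sequence)
  preds <- vapply(panel, function(pk)
    as.numeric(solve_pi_matrix(m, pk, precision = precision)),
    numeric(nrow(records)))
  if (nrow(records) == 1L) preds <- matrix(preds, nrow = 1L)
  rowMeans(preds)
}

#' Remove annotation-error outliers
#'
#' A record is an outlier when the squared difference between its
#' experimental consensus pI and the average pI predicted by a panel of
#' literature pKa sets exceeds `mse_threshold` (strict `>`). The default
#' threshold 3 (proteins) corresponds to an absolute deviation of about
#' 1.73 pH units; use 0.25 for peptides (0.5 pH units). The default panel
#' excludes the simplified Patrickios set and the optimized IPC sets.
#'
#' @param records A `pi_dataset` with `consensus_pi` set (run
#'   [merge_and_average()] first).
#' @param mse_threshold Squared-deviation threshold.
#' @param panel pKa sets (labels or `pka_set` objects) defining the
#'   consensus prediction.
#' @return List with `kept` (a `pi_dataset`) and `removed` (data frame with
#'   `id`, `consensus_pi`, `predicted_pi`, `delta`).
#' @export
remove_outliers <- function(records, mse_threshold = 3,
                            panel = default_consensus_panel()) {
  stopifnot(inherits(records, "pi_dataset"))
  if (!length(panel)) stop("empty consensus panel", call. = FALSE)
  if (anyNA(records$consensus_pi)) {
    stop("all records need a consensus_pi; run merge_and_average() first",
         call. = FALSE)
  }
  if (!nrow(records)) {
    return(list(kept = records,
                removed = data.frame(id = character(0), consensus_pi = numeric(0),
                                     predicted_pi = numeric(0), delta = numeric(0))))
  }
  pred <- panel_mean_pi(records, panel)
  delta <- records$consensus_pi - pred
  out <- delta^2 > mse_threshold
  list(
    kept = records[!out, , drop = FALSE],
    removed = data.frame(id = records$id[out],
                         consensus_pi = records$consensus_pi[out],
                         predicted_pi = pred[out],
                         delta = delta[out])
  )
}

# ungapped end-anchored global identity: matching positions over the length
# of the shorter sequence. Adequate for near-identical pairs at thresholds
# around 0.99, where a real alignment engine adds nothing.
seq_identity <- function(a, b) {
  la <- nchar(a); lb <- nchar(b)
  n <- min(la, lb)
  if (n == 0L) return(0)
  ca <- utf8ToInt(substr(a, 1L, n))
  cb <- utf8ToInt(substr(b, 1L, n))
  sum(ca == cb) / n
}

#' Cluster near-identical sequences and keep one representative
#'
#' Greedy incremental clustering in decreasing length order, the scheme used
#' by CD-HIT: a record joins the first existing cluster whose (longest)
#' representative it matches at global identity >= `identity_threshold`;
#' otherwise it founds a new cluster. Identity is the fraction of matching
#' positions over the shorter sequence, end-anchored and ungapped.
#'
#' @param records A `pi_dataset`.
#' @param identity_threshold Global identity above which two sequences are
#'   redundant (default 0.99).
#' @return List with `representatives` (a `pi_dataset`) and `removed`
#'   (data frame with `id`, `representative_id`, `identity`).
#' @export
cluster_redundant <- function(records, identity_threshold = 0.99) {
  stopifnot(inherits(records, "pi_dataset"),
            identity_threshold > 0, identity_threshold <= 1)
  n <- nrow(records)
  ord <- order(-nchar(records$sequence))
  rep_idx <- integer(0)
  removed <- list()
  for (i in ord) {
    s <- records$sequence[i]
    assigned <- FALSE
    for (j in rep_idx) {
      idt <- seq_identity(s, records$sequence[j])
      if (idt >= identity_threshold) {
        removed[[length(removed) + 1L]] <-
          data.frame(id = records$id[i], representative_id = records$id[j],
                     identity = idt)
        assigned <- TRUE
        break
      }
    }
    if (!assigned) rep_idx <- c(rep_idx, i)
  }
  keep <- sort(rep_idx)
  list(
    representatives = records[keep, , drop = FALSE],
    removed = if (length(removed)) do.call(rbind, removed)
              else data.frame(id = character(0), representative_id = character(0),
                              identity = numeric(0))
  )
}

#' Random train/test split
#'
#' @param records A `pi_dataset` with at least 2 records.
#' @param train_fraction Fraction assigned to training (default 0.75;
#'   `|train| = round(train_fraction * N)`).
#' @param seed Integer seed making the assignment reproducible.
#' @return The dataset with an added `split` column (`"train"`/`"test"`).
#' @export
split_train_test <- function(records, train_fraction = 0.75, seed = 1L) {
  stopifnot(inherits(records, "pi_dataset"),
            train_fraction > 0, train_fraction < 1)
  n <- nrow(records)
  if (n < 2L) stop("need at least 2 records to split", call. = FALSE)
  n_train <- round(train_fraction * n)
  n_train <- max(1L, min(n - 1L, n_train))
  train_idx <- with_local_seed(seed, sample.int(n, n_train))
  records$split <- ifelse(seq_len(n) %in% train_idx, "train", "test")
  records
}

# run `expr` under a local RNG state seeded with `seed`
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Full curation pipeline
#'
#' Convenience wrapper: [merge_and_average()] then [remove_outliers()] then
#' [cluster_redundant()]. Record counts at every stage reconcile:
#' `n_input = n_dropped_no_pi + n_merged + n_outliers + n_redundant + n_kept`.
#'
#' @inheritParams remove_outliers
#' @inheritParams cluster_redundant
#' @return List with `records` (curated `pi_dataset`), `report` (data frame
#'   `id`, `action`, `detail`) and `counts` (named integer vector of the
#'   stage tallies).
#' @export
curate_dataset <- function(records, mse_threshold = 3,
                           panel = default_consensus_panel(),
                           identity_threshold = 0.99) {
  n_input <- nrow(records)
  merged <- merge_and_average(records)
  o <- remove_outliers(merged, mse_threshold = mse_threshold, panel = panel)
  cl <- cluster_redundant(o$kept, identity_threshold = identity_threshold)
  report <- rbind(
    if (nrow(o$removed))
      data.frame(id = o$removed$id, action = "outlier",
                 detail = sprintf("delta=%.4f", o$removed$delta)),
    if (nrow(cl$removed))
      data.frame(id = cl$removed$id, action = "redundant",
                 detail = sprintf("representative=%s",
                                  cl$removed$representative_id))
  )
  if (is.null(report))
    report <- data.frame(id = character(0), action = character(0),
                         detail = character(0))
  counts <- c(input = n_input,
              dropped_no_pi = attr(merged, "n_dropped_no_pi") %||% 0L,
              merged = attr(merged, "n_merged") %||% 0L,
              outliers = nrow(o$removed),
              redundant = nrow(cl$removed),
              kept = nrow(cl$representatives))
  list(records = cl$representatives, report = report, counts = counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
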
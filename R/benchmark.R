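# Benchmarking of pKa sets against experimentally measured pI values:
# RMSD, percent difference between methods, outlier counts at a squared
# error threshold, per-record consensus ("Avg_pI") and Pearson diagnostics.

#' Predict pI for every record of a dataset
#'
#' @param records A `pi_dataset`.
#' @param pka One pKa set (label or `pka_set`) or a list/vector of several.
#' @param precision Bisection precision in pH units.
#' @return A data frame with column `id` and one numeric pI column per set.
#' @export
predict_pi <- function(records, pka = list_pka_sets(), precision = 0.001) {
  stopifnot(inherits(records, "pi_dataset"))
  panel <- as_pka_panel(pka)
  m <- count_matrix(records$sequence)
  out <- data.frame(id = records$id, stringsAsFactors = FALSE)
  for (nm in names(panel)) {
    out[[nm]] <- as.numeric(solve_pi_matrix(m, panel[[nm]],
                                            precision = precision))
  }
  out
}

#' Root-mean-square deviation between predicted and experimental pI
#'
#' @param predicted,experimental Equal-length numeric vectors (pH units).
#' @return `sqrt(mean((predicted - experimental)^2))`.
#' @export
rmsd <- function(predicted, experimental) {
  if (length(predicted) != length(experimental)) {
    stop("predicted and experimental differ in length", call. = FALSE)
  }
  if (!length(predicted)) stop("empty input", call. = FALSE)
  sqrt(mean((predicted - experimental)^2))
}

#' Percent difference between two RMSD values
#'
#' The pH scale is base-10 logarithmic, so the relative difference between
#' two error estimates expressed in pH units is
#' `100 * (10^(rmsd_method - rmsd_reference) - 1)` percent.
#'
#' @param rmsd_method,rmsd_reference Non-negative RMSD values (pH units).
#' @return Percent difference (0 when the two are equal).
#' @export
#' @examples
#' percent_difference(0.945, 0.874)  # 17.8 to one decimal
percent_difference <- function(rmsd_method, rmsd_reference) {
  stopifnot(all(rmsd_method >= 0), all(rmsd_reference >= 0))
  100 * (10^(rmsd_method - rmsd_reference) - 1)
}

#' Count prediction outliers at a squared-error threshold
#'
#' @param predicted,experimental Equal-length numeric vectors.
#' @param mse_threshold Squared-error threshold: record `i` is an outlier
#'   when `(predicted[i] - experimental[i])^2 > mse_threshold` (strict).
#'   Use 3 for proteins, 0.25 for peptides.
#' @return Integer count.
#' @export
count_outliers <- function(predicted, experimental, mse_threshold) {
  if (length(predicted) != length(experimental)) {
    stop("predicted and experimental differ in length", call. = FALSE)
  }
  sum((predicted - experimental)^2 > mse_threshold)
}

#' Per-record consensus pI over a panel of pKa sets
#'
#' The consensus ("Avg_pI") is computed per individual record: the
#' arithmetic mean of the pI predicted by every panel member for that
#' record. By default the panel excludes the simplified Patrickios set and
#' the optimized IPC sets.
#'
#' @param x An amino-acid string, `ionizable_counts`, or `pi_dataset`.
#' @param panel pKa sets (labels or objects).
#' @param precision Bisection precision.
#' @return For a single sequence, one number; for a `pi_dataset`, a numeric
#'   vector with one entry per record.
#' @export
avg_pi_consensus <- function(x, panel = default_consensus_panel(),
                             precision = 0.001) {
  if (!length(panel)) stop("empty consensus panel", call. = FALSE)
  if (inherits(x, "pi_dataset")) {
    return(panel_mean_pi(x, panel, precision = precision))
  }
  panel <- as_pka_panel(panel)
  preds <- vapply(panel, function(pk)
    isoelectric_point(x, pk, precision = precision)$pi, 0)
  mean(preds)
}

#' Squared Pearson correlation (diagnostic only)
#'
#' R-squared measures linear association, not prediction accuracy; it is
#' reported as a preliminary diagnostic, never as a performance measure.
#'
#' @param predicted,experimental Equal-length numeric vectors, length >= 3.
#' @return Squared Pearson correlation coefficient.
#' @export
pearson_r2 <- function(predicted, experimental) {
  if (length(predicted) != length(experimental)) {
    stop("predicted and experimental differ in length", call. = FALSE)
  }
  if (length(predicted) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(predicted) == 0 || stats::sd(experimental) == 0) {
    stop("degenerate input: zero variance", call. = FALSE)
  }
  stats::cor(predicted, experimental)^2
}

#' Benchmark a panel of pKa sets on a curated dataset
#'
#' Scores every pKa set against the experimental consensus pI of the
#' dataset and appends an `Avg_pI` row for the per-record consensus over
#' `consensus_panel`. Methods are sorted by ascending RMSD (ties broken by
#' registry order); the percent column is relative to the best method.
#'
#' @param records A `pi_dataset` with `consensus_pi` set.
#' @param pka pKa sets to score (labels or objects).
#' @param mse_threshold Outlier threshold (3 proteins / 0.25 peptides).
#' @param consensus_panel Sets defining the `Avg_pI` row; `NULL` to omit it.
#' @param precision Bisection precision.
#' @return A `benchmark_table` data frame: `method`, `rmsd`,
#'   `percent_vs_best`, `n_outliers`, `n_records`, `r2`.
#' @export
benchmark_table <- function(records, pka = list_pka_sets(),
                            mse_threshold = 3,
                            consensus_panel = default_consensus_panel(),
                            precision = 0.001) {
  stopifnot(inherits(records, "pi_dataset"))
  if (anyNA(records$consensus_pi)) {
    stop("all records need a consensus_pi; run merge_and_average() first",
         call. = FALSE)
  }
  panel <- as_pka_panel(pka)
  exp_pi <- records$consensus_pi
  m <- count_matrix(records$sequence)
  safe_r2 <- function(p, e) {
    if (length(e) >= 3L && stats::sd(p) > 0 && stats::sd(e) > 0)
      pearson_r2(p, e) else NA_real_
  }
  score_one <- function(pred, nm) {
    inlier <- (pred - exp_pi)^2 <= mse_threshold
    data.frame(method = nm,
               rmsd = rmsd(pred, exp_pi),
               percent_vs_best = NA_real_,
               n_outliers = count_outliers(pred, exp_pi, mse_threshold),
               n_records = length(exp_pi),
               r2 = safe_r2(pred, exp_pi),
               r2_corr = safe_r2(pred[inlier], exp_pi[inlier]))
  }
  rows <- lapply(names(panel), function(nm) {
    pred <- as.numeric(solve_pi_matrix(m, panel[[nm]], precision = precision))
    score_one(pred, nm)
  })
  tab <- do.call(rbind, rows)
  # stable sort: ties keep the order the sets were supplied in
  tab <- tab[order(tab$rmsd), , drop = FALSE]
  if (!is.null(consensus_panel) && length(consensus_panel)) {
    cons <- panel_mean_pi(records, consensus_panel, precision = precision)
    tab <- rbind(tab, score_one(cons, "Avg_pI"))
  }
  tab$percent_vs_best <- percent_difference(tab$rmsd, min(tab$rmsd))
  rownames(tab) <- NULL
  class(tab) <- c("benchmark_table", "data.frame")
  tab
}

#' @export
print.benchmark_table <- function(x, ...) {
  fmt <- data.frame(Method = x$method,
                    RMSD = sprintf("%.4f", x$rmsd),
                    `%` = sprintf("%.1f", x$percent_vs_best),
                    Outliers = x$n_outliers,
                    check.names = FALSE)
  print(fmt, row.names = FALSE)
  invisible(x)
}

#' Write a benchmark table as TSV
#'
#' @param tab A `benchmark_table`.
#' @param path Output path (TSV with full-precision numbers).
#' @return `path`, invisibly.
#' @export
write_benchmark_tsv <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
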
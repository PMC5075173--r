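# Synthetic pI-labeled sequence fixtures.
#
# Emulates the statistical structure of experimental pI compilations:
# replicate measurements of the same sequence, duplicate database entries,
# Gaussian measurement noise, and a controllable fraction of gross
# annotation errors (outliers) placed far enough from the consensus
# prediction that the squared-error > 3 curation rule is guaranteed to
# catch them. Everything is reproducible from a single integer seed.

# uncharged background alphabet; charged positions draw from the seven
# ionizable letters
AA_BACKGROUND <- c("A", "G", "L", "S", "T", "V", "P", "F", "W", "M",
                   "N", "Q", "I")

#' Specification of a synthetic pI-labeled dataset
#'
#' @param n_records Number of base records.
#' @param length_range Length-2 integer vector: inclusive residue-count
#'   range of the generated sequences.
#' @param charged_fraction Probability that a position carries one of the
#'   seven ionizable residues (C, D, E, H, K, R, Y); roughly 0.25 in natural
#'   proteins.
#' @param label_pka_set The pKa set (label or `pka_set`) whose predicted pI
#'   is the ground-truth label.
#' @param noise_sigma Standard deviation of Gaussian measurement noise added
#'   to each reported pI, in pH units.
#' @param replicate_probability Probability a record reports two independent
#'   measurements in one header.
#' @param outlier_fraction Fraction of records whose label is shifted by a
#'   gross error (uniform 2-4 pH units away from the consensus-panel
#'   prediction, clamped to (0, 14)).
#' @param duplicate_fraction Fraction of records additionally emitted a
#'   second time, as a separate record with the same sequence and a fresh
#'   measurement draw (duplicate database entries).
#' @param rng_seed Integer seed.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_records = 100L,
                         length_range = c(7L, 30L),
                         charged_fraction = 0.25,
                         label_pka_set = "IPC_peptide",
                         noise_sigma = 0.25,
                         replicate_probability = 0.1,
                         outlier_fraction = 0,
                         duplicate_fraction = 0,
                         rng_seed = 1L) {
  stopifnot(n_records >= 1L,
            length(length_range) == 2L, all(length_range >= 1L),
            length_range[1] <= length_range[2],
            charged_fraction >= 0, charged_fraction <= 1,
            noise_sigma >= 0,
            replicate_probability >= 0, replicate_probability <= 1,
            outlier_fraction >= 0, outlier_fraction <= 1,
            duplicate_fraction >= 0, duplicate_fraction <= 1,
            outlier_fraction + duplicate_fraction <= 1)
  structure(
    list(n_records = as.integer(n_records),
         length_range = as.integer(length_range),
         charged_fraction = charged_fraction,
         label_pka_set = as_pka_set(label_pka_set),
         noise_sigma = noise_sigma,
         replicate_probability = replicate_probability,
         outlier_fraction = outlier_fraction,
         duplicate_fraction = duplicate_fraction,
         rng_seed = as.integer(rng_seed)),
    class = "fixture_spec"
  )
}

clamp_ph <- function(x, eps = 0.05) pmin(pmax(x, eps), 14 - eps)

#' Generate a synthetic pI-labeled dataset
#'
#' Sequences are random strings over the 20-letter alphabet with ionizable
#' letters placed at `charged_fraction` of positions. The ground-truth label
#' of each record is its solver pI under `label_pka_set`; reported
#' measurements add Gaussian noise. Designated outlier records get their
#' label shifted 2-4 pH units away from the consensus-panel prediction so
#' the squared-error > 3 filter finds exactly them; designated duplicate
#' records appear twice with independent measurements.
#'
#' @param spec A [fixture_spec()].
#' @param outlier_panel pKa sets defining the consensus prediction that the
#'   planted outliers are shifted away from (default: the standard
#'   consensus panel).
#' @return A [pi_dataset()] with attributes `clean_pi` (named true labels of
#'   the base records), `outlier_ids`, `duplicate_ids` and `label_pka_set`.
#' @export
generate_fixture <- function(spec, outlier_panel = default_consensus_panel()) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_local_seed(spec$rng_seed, {
    n <- spec$n_records
    lens <- sample(seq(spec$length_range[1], spec$length_range[2]),
                   n, replace = TRUE)
    seqs <- vapply(lens, function(L) {
      charged <- stats::runif(L) < spec$charged_fraction
      chars <- character(L)
      chars[charged] <- sample(IONIZABLE_LETTERS, sum(charged), replace = TRUE)
      chars[!charged] <- sample(AA_BACKGROUND, sum(!charged), replace = TRUE)
      paste(chars, collapse = "")
    }, "")
    # duplicated sequences would merge unintentionally; regenerate clashes
    while (anyDuplicated(seqs)) {
      i <- which(duplicated(seqs))
      seqs[i] <- vapply(lens[i], function(L)
        paste(sample(c(AA_BACKGROUND, IONIZABLE_LETTERS), L, replace = TRUE),
              collapse = ""), "")
    }
    ids <- sprintf("SYN%05d", seq_len(n))
    m <- count_matrix(seqs)
    clean <- as.numeric(solve_pi_matrix(m, spec$label_pka_set))

    n_dup <- round(spec$duplicate_fraction * n)
    n_out <- round(spec$outlier_fraction * n)
    dup_idx <- if (n_dup > 0) sort(sample.int(n, n_dup)) else integer(0)
    out_pool <- setdiff(seq_len(n), dup_idx)
    out_idx <- if (n_out > 0) sort(sample(out_pool, n_out)) else integer(0)

    label <- clean
    if (n_out > 0) {
      pred <- rowMeans(vapply(as_pka_panel(outlier_panel), function(pk)
        as.numeric(solve_pi_matrix(m[out_idx, , drop = FALSE], pk)),
        numeric(n_out)))
      dir <- ifelse(clean[out_idx] >= pred, 1, -1)
      shift <- abs(clean[out_idx] - pred) + stats::runif(n_out, 2, 4)
      shifted <- clamp_ph(pred + dir * shift)
      # clamping at a pH-scale edge can pull the error back under the
      # detection threshold; those records are shifted the other way
      flip <- abs(shifted - pred) < 2
      shifted[flip] <- clamp_ph(pred[flip] - dir[flip] * shift[flip])
      label[out_idx] <- shifted
    }

    draw <- function(mu, k) clamp_ph(mu + stats::rnorm(k, sd = spec$noise_sigma))
    two <- stats::runif(n) < spec$replicate_probability
    pis <- lapply(seq_len(n), function(i)
      draw(label[i], if (two[i]) 2L else 1L))

    if (n_dup > 0) {
      dup_ids <- paste0(ids[dup_idx], "_r2")
      dup_pis <- lapply(dup_idx, function(i) draw(label[i], 1L))
      ids <- c(ids, dup_ids)
      seqs <- c(seqs, seqs[dup_idx])
      pis <- c(pis, dup_pis)
    }

    out <- pi_dataset(ids, seqs, pis, source = "synthetic")
    attr(out, "clean_pi") <- stats::setNames(clean, sprintf("SYN%05d", seq_len(n)))
    attr(out, "outlier_ids") <- sprintf("SYN%05d", out_idx)
    attr(out, "duplicate_ids") <- sprintf("SYN%05d", dup_idx)
    attr(out, "label_pka_set") <- spec$label_pka_set$name
    out
  })
}

#' Peptide-like and protein-like fixture presets
#'
#' `generate_peptide_like()` draws short sequences (7-30 residues, the
#' tryptic-peptide regime, labels under IPC_peptide); `generate_protein_like()`
#' draws long ones (100-1000 residues, labels under IPC_protein). All other
#' [fixture_spec()] fields are forwarded.
#'
#' @param n_records Number of base records.
#' @param rng_seed Integer seed.
#' @param ... Further arguments to [fixture_spec()].
#' @return A [pi_dataset()], as [generate_fixture()].
#' @export
generate_peptide_like <- function(n_records = 100L, rng_seed = 1L, ...) {
  generate_fixture(fixture_spec(n_records = n_records,
                                length_range = c(7L, 30L),
                                label_pka_set = "IPC_peptide",
                                rng_seed = rng_seed, ...))
}

#' @rdname generate_peptide_like
#' @export
generate_protein_like <- function(n_records = 100L, rng_seed = 1L, ...) {
  generate_fixture(fixture_spec(n_records = n_records,
                                length_range = c(100L, 1000L),
                                label_pka_set = "IPC_protein",
                                rng_seed = rng_seed, ...))
}
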
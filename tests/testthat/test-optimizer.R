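# Basin-hopping pKa optimization: cost, bounded local descent, hops,
# cross-validation, multi-seed. Scaled-down versions of the full recovery
# run (which lives in the acceptance suite) keep this file fast.

peptide_data <- function(n, hidden, noise = 0, seed = 1) {
  merge_and_average(generate_fixture(fixture_spec(
    n_records = n, length_range = c(7L, 30L), label_pka_set = hidden,
    noise_sigma = noise, replicate_probability = 0, rng_seed = seed)))
}

hidden_set <- function(offsets = c(NTERM = 0.35, CTERM = -0.3, C = 0.4,
                                   D = -0.25, E = 0.3, H = -0.35, K = 0.3,
                                   R = -0.4, Y = 0.45),
                       base = "IPC_peptide") {
  pka_set(get_pka_set(base)$values + offsets, name = "hidden")
}

test_that("cost is zero on self-labeled data and positive after a shift", {
  d <- peptide_data(50, get_pka_set("EMBOSS"), seed = 2)
  expect_equal(pi_cost(get_pka_set("EMBOSS"), d), 0)
  shifted <- pka_set(get_pka_set("EMBOSS")$values + 1, name = "shifted")
  expect_gt(pi_cost(shifted, d), 0)
})

test_that("cost equals the RMSD of per-record solver outputs", {
  d <- peptide_data(50, hidden_set(), noise = 0.2, seed = 3)
  pred <- vapply(d$sequence, function(s)
    isoelectric_point(s, "EMBOSS")$pi, 0, USE.NAMES = FALSE)
  expect_equal(pi_cost(get_pka_set("EMBOSS"), d),
               rmsd(pred, d$consensus_pi), tolerance = 1e-12)
})

test_that("local minimization satisfies the bounded-descent contract", {
  d <- peptide_data(150, hidden_set(), seed = 4)
  start <- get_pka_set("IPC_peptide")$values + 0.3
  f0 <- pi_cost(start, d, precision = 1e-5)
  res <- local_minimize(start, d, bound_width = 2, max_iter = 50)
  expect_lt(res$value, f0)                     # strict descent from offset start
  expect_true(all(res$par >= start - 2 - 1e-9 & res$par <= start + 2 + 1e-9))

  # a start already at the global optimum of noise-free data stays put
  d0 <- peptide_data(80, get_pka_set("EMBOSS"), seed = 5)
  at_opt <- local_minimize(get_pka_set("EMBOSS"), d0, max_iter = 30)
  expect_equal(at_opt$value, 0, tolerance = 1e-3)
  expect_equal(unname(at_opt$par), unname(get_pka_set("EMBOSS")$values),
               tolerance = 0.02)
})

test_that("one-group peptides recover the generating termini midpoint", {
  # glycine-only sequences: pI depends on the pKa vector solely through
  # (NTERM + CTERM) / 2, a closed-form valley
  hid <- hidden_set()
  mid_hidden <- (hid$values[["NTERM"]] + hid$values[["CTERM"]]) / 2
  d <- pi_dataset(sprintf("g%d", 4:23),
                  vapply(4:23, function(k) strrep("G", k), ""),
                  as.list(rep(mid_hidden, 20)))
  d$consensus_pi <- rep(mid_hidden, 20)
  res <- local_minimize(get_pka_set("IPC_peptide"), d, max_iter = 60)
  mid_rec <- (res$par[["NTERM"]] + res$par[["CTERM"]]) / 2
  expect_equal(mid_rec, mid_hidden, tolerance = 1e-3)
  expect_equal(res$value, 0, tolerance = 1e-3)
})

test_that("basin_hop with one hop equals a single local minimization", {
  d <- peptide_data(60, hidden_set(), seed = 6)
  cfg <- optimizer_config(seeds = "IPC_peptide", n_hops = 1L,
                          local_max_iter = 40L, rng_seed = 99L)
  bh <- basin_hop(cfg, d)
  lm <- local_minimize(get_pka_set("IPC_peptide"), d,
                       lower = bh$lower, upper = bh$upper, max_iter = 40L)
  expect_equal(bh$par, lm$par)
  expect_equal(bh$value, lm$value)
  expect_equal(nrow(bh$trace), 1L)
})

test_that("basin_hop is reproducible and respects its bounds", {
  d <- peptide_data(60, hidden_set(), noise = 0.25, seed = 7)
  cfg <- optimizer_config(seeds = "IPC_peptide", n_hops = 3L,
                          local_max_iter = 25L, rng_seed = 42L,
                          step_size = 0.3)
  a <- basin_hop(cfg, d)
  b <- basin_hop(cfg, d)
  expect_identical(a$trace, b$trace)
  expect_identical(a$par, b$par)
  expect_true(all(a$par >= a$lower - 1e-9 & a$par <= a$upper + 1e-9))
  # best-so-far trace is non-increasing
  expect_true(all(diff(a$trace$best) <= 1e-12))
  expect_error(basin_hop(cfg, d[1:5, ]), "at least 10")
})

test_that("cross-validation averages the per-fold solutions", {
  d <- peptide_data(30, get_pka_set("EMBOSS"), seed = 8)
  cfg <- optimizer_config(seeds = "EMBOSS", n_hops = 1L, n_folds = 2L,
                          local_max_iter = 20L, rng_seed = 3L)
  res <- cross_validated_optimize(cfg, d)
  expect_equal(nrow(res$per_fold_pars), 2L)
  expect_equal(unname(res$final_set$values),
               unname(colMeans(res$per_fold_pars)))
  # noise-free self-consistent data: everything near zero
  expect_lt(res$train_rmsd, 0.01)
  expect_lt(res$cv_rmsd, 0.01)
  expect_error(cross_validated_optimize(cfg, d[1:1, ]), "fewer records")
})

test_that("held-out cost exceeds training cost on average under noise", {
  cfg <- optimizer_config(seeds = "IPC_peptide", n_hops = 1L, n_folds = 2L,
                          local_max_iter = 30L, rng_seed = 1L)
  gaps <- vapply(1:5, function(r) {
    d <- peptide_data(50, hidden_set(), noise = 0.3, seed = 100 + r)
    cfg$rng_seed <- r
    res <- cross_validated_optimize(cfg, d)
    res$cv_rmsd - res$train_rmsd
  }, 0)
  expect_gt(mean(gaps), 0)
})

test_that("multi_seed_optimize picks the best seed deterministically", {
  d <- peptide_data(60, hidden_set(), noise = 0.2, seed = 9)
  cfg1 <- optimizer_config(seeds = "IPC_peptide", n_hops = 1L, n_folds = 2L,
                           local_max_iter = 25L, rng_seed = 5L,
                           n_restarts = 1L)
  single <- cross_validated_optimize(cfg1, d)
  ms1 <- multi_seed_optimize(cfg1, d)
  expect_equal(ms1$final_set$values, single$final_set$values)
  expect_equal(ms1$cv_rmsd, single$cv_rmsd)

  # two seeds, data generated near IPC_peptide: winner starts from it
  cfg2 <- optimizer_config(seeds = c("IPC_peptide", "Nozaki"), n_hops = 1L,
                           n_folds = 2L, local_max_iter = 25L, rng_seed = 5L,
                           n_restarts = 1L)
  ms2a <- multi_seed_optimize(cfg2, d)
  ms2b <- multi_seed_optimize(cfg2, d)
  expect_identical(ms2a$final_set$values, ms2b$final_set$values)
  expect_equal(ms2a$n_runs, 2L)
})

test_that("simplified seeds and bad configs are rejected", {
  expect_error(optimizer_config(seeds = "Patrickios"), "non-ionizing")
  expect_error(optimizer_config(n_folds = 1L))
  expect_error(optimizer_config(bound_width = 0))
})

test_that("scaled-down parameter recovery from a hidden set", {
  hid <- hidden_set()
  d <- peptide_data(400, hid, seed = 10)
  res <- local_minimize(get_pka_set("IPC_peptide"), d, max_iter = 100)
  expect_lt(max(abs(res$par - hid$values)), 0.05)
})
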
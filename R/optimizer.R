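# Derivation of optimized pKa sets from pI-labeled datasets.
#
# The cost of a candidate nine-parameter pKa vector is the RMSD between the
# experimental pI labels and the pI computed with that vector. The global
# search is basin-hopping: random perturbations of the current solution,
# each refined by a bounded local minimizer and accepted by the Metropolis
# criterion; parameters are constrained to +/- bound_width (default 2 pH
# units) around the seed set. Training uses nested 10-fold cross-validation
# and the per-fold solutions are averaged into the final set.

#' Optimizer configuration
#'
#' @param seeds Seed pKa sets: labels or `pka_set` objects (all nine values
#'   must be present; simplified sets with non-ionizing groups cannot seed).
#' @param bound_width Half-width of the box around each seed value within
#'   which the search is confined, in pH units.
#' @param n_hops Total number of local minimizations per basin-hopping run
#'   (1 = a single bounded local minimization from the seed).
#' @param mc_temperature Metropolis temperature, in cost (pH RMSD) units.
#' @param step_size Uniform perturbation half-width between hops, pH units.
#' @param local_max_iter Iteration cap for each local minimization.
#' @param n_folds Cross-validation folds.
#' @param rng_seed Integer seed; every random draw in the optimizer derives
#'   from it.
#' @param n_restarts Independent basin-hopping restarts per seed in
#'   [multi_seed_optimize()].
#' @param solver_precision Bisection precision used inside the cost
#'   function. Finer than the reporting default so that finite-difference
#'   gradients see a smooth surface rather than solver quantization.
#' @return An `optimizer_config` list.
#' @export
optimizer_config <- function(seeds = list("EMBOSS"),
                             bound_width = 2.0,
                             n_hops = 100L,
                             mc_temperature = 1.0,
                             step_size = 0.25,
                             local_max_iter = 100L,
                             n_folds = 10L,
                             rng_seed = 1L,
                             n_restarts = 10L,
                             solver_precision = 1e-5) {
  stopifnot(bound_width > 0, n_hops >= 1L, n_folds >= 2L, n_restarts >= 1L,
            step_size > 0, mc_temperature > 0, solver_precision > 0)
  if (inherits(seeds, "pka_set") || is.character(seeds)) seeds <- as.list(seeds)
  seeds <- lapply(seeds, as_pka_set)
  for (s in seeds) {
    if (anyNA(s$values)) {
      stop("seed set '", s$name, "' has non-ionizing (NA) groups and cannot ",
           "seed a nine-parameter optimization", call. = FALSE)
    }
  }
  structure(
    list(seeds = seeds, bound_width = bound_width, n_hops = as.integer(n_hops),
         mc_temperature = mc_temperature, step_size = step_size,
         local_max_iter = as.integer(local_max_iter),
         n_folds = as.integer(n_folds), rng_seed = as.integer(rng_seed),
         n_restarts = as.integer(n_restarts),
         solver_precision = solver_precision),
    class = "optimizer_config"
  )
}

# accept a pka_set or a bare length-9 vector as a parameter vector
as_par_vector <- function(pka) {
  if (inherits(pka, "pka_set")) pka <- pka$values
  stopifnot(is.numeric(pka), length(pka) == 9L)
  if (is.null(names(pka))) names(pka) <- PKA_GROUPS
  pka[PKA_GROUPS]
}

# internal fast path: cost against a precomputed count matrix
cost_matrix <- function(par, m, y, precision) {
  pk <- new_pka_set(as.numeric(par), name = "candidate")
  pred <- as.numeric(solve_pi_matrix(m, pk, precision = precision,
                                     check_root = FALSE))
  sqrt(mean((pred - y)^2))
}

#' Optimization cost of a candidate pKa vector
#'
#' RMSD, in pH units, between the experimental consensus pI of a curated
#' dataset and the pI computed under the candidate parameters.
#'
#' @param pka A `pka_set` or a named length-9 numeric vector
#'   (`NTERM, CTERM, C, D, E, H, K, R, Y`).
#' @param records A `pi_dataset` with `consensus_pi` set.
#' @param precision Bisection precision of the pI solver.
#' @return The RMSD (non-negative scalar).
#' @export
pi_cost <- function(pka, records, precision = 0.001) {
  stopifnot(inherits(records, "pi_dataset"))
  if (anyNA(records$consensus_pi)) {
    stop("all records need a consensus_pi", call. = FALSE)
  }
  cost_matrix(as_par_vector(pka), count_matrix(records$sequence),
              records$consensus_pi, precision)
}

# clamp a box to the physically meaningful open interval (0, 14)
clamp_bounds <- function(lower, upper) {
  list(lower = pmax(lower, 1e-3), upper = pmin(upper, 14 - 1e-3))
}

# bounded local minimization (quasi-Newton, finite-difference gradients).
# Contract: result within [lower, upper], cost(result) <= cost(start).
local_minimize_matrix <- function(start, lower, upper, m, y, precision,
                                  max_iter = 100L) {
  fn <- function(p) cost_matrix(p, m, y, precision)
  res <- tryCatch(
    stats::optim(start, fn, method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(maxit = max_iter, factr = 1e5)),
    error = function(e) list(par = start, value = fn(start), convergence = 99L)
  )
  f0 <- fn(start)
  if (res$value > f0) {           # descent contract: never return worse
    res$par <- start
    res$value <- f0
  }
  res$par <- pmin(pmax(res$par, lower), upper)
  names(res$par) <- PKA_GROUPS
  res
}

#' Bounded local minimization of the pKa cost
#'
#' Refines a candidate pKa vector with a bounded quasi-Newton minimizer
#' (finite-difference gradients through the bisection solver). The result
#' never has higher cost than the start.
#'
#' @param start Starting `pka_set` or named length-9 vector.
#' @param records A `pi_dataset` with `consensus_pi` set.
#' @param lower,upper Optional explicit bounds (length 9); default
#'   `start +/- bound_width` clamped to (0, 14).
#' @param bound_width Box half-width when `lower`/`upper` are not given.
#' @param max_iter Iteration cap.
#' @param precision Solver precision inside the cost.
#' @return List with `par` (named vector), `value` (cost at `par`) and
#'   `convergence` (0 = converged; best-so-far is returned regardless).
#' @export
local_minimize <- function(start, records, lower = NULL, upper = NULL,
                           bound_width = 2.0, max_iter = 100L,
                           precision = 1e-5) {
  start <- as_par_vector(start)
  if (is.null(lower) || is.null(upper)) {
    b <- clamp_bounds(start - bound_width, start + bound_width)
    lower <- lower %||% b$lower
    upper <- upper %||% b$upper
  }
  stopifnot(all(start >= lower - 1e-12), all(start <= upper + 1e-12))
  local_minimize_matrix(start, lower, upper,
                        count_matrix(records$sequence), records$consensus_pi,
                        precision, max_iter = max_iter)
}

# one basin-hopping run against precomputed data; RNG state is the caller's
basin_hop_matrix <- function(seed_par, lower, upper, m, y, config) {
  res <- local_minimize_matrix(seed_par, lower, upper, m, y,
                               config$solver_precision,
                               max_iter = config$local_max_iter)
  cur_par <- best_par <- res$par
  cur_val <- best_val <- res$value
  trace <- data.frame(hop = 0L, cost = cur_val, best = best_val)
  if (config$n_hops > 1L) {
    for (k in seq_len(config$n_hops - 1L)) {
      prop <- cur_par + stats::runif(9L, -config$step_size, config$step_size)
      prop <- pmin(pmax(prop, lower), upper)
      res <- local_minimize_matrix(prop, lower, upper, m, y,
                                   config$solver_precision,
                                   max_iter = config$local_max_iter)
      accept <- res$value <= cur_val ||
        stats::runif(1L) < exp(-(res$value - cur_val) / config$mc_temperature)
      if (accept) {
        cur_par <- res$par
        cur_val <- res$value
      }
      if (res$value < best_val) {
        best_par <- res$par
        best_val <- res$value
      }
      trace <- rbind(trace,
                     data.frame(hop = k, cost = cur_val, best = best_val))
    }
  }
  list(par = best_par, value = best_val, trace = trace)
}

#' Basin-hopping optimization of a pKa set (single run)
#'
#' Runs `n_hops` bounded local minimizations: the first from the seed, each
#' subsequent one from a uniform random perturbation of the current
#' solution, accepted by the Metropolis criterion at `mc_temperature`. The
#' best solution ever seen is returned. Reproducible given `rng_seed`.
#'
#' @param config An [optimizer_config()] (its first seed is used).
#' @param records A `pi_dataset` with `consensus_pi` set, >= 10 records.
#' @return List with `par` (named length-9 vector), `value` (cost), `trace`
#'   (data frame `hop`, `cost`, `best`), `seed_name`, `lower`, `upper`.
#' @export
basin_hop <- function(config, records) {
  stopifnot(inherits(config, "optimizer_config"),
            inherits(records, "pi_dataset"))
  if (nrow(records) < 10L) stop("need at least 10 records", call. = FALSE)
  if (anyNA(records$consensus_pi)) {
    stop("all records need a consensus_pi", call. = FALSE)
  }
  seed_par <- as_par_vector(config$seeds[[1L]])
  b <- clamp_bounds(seed_par - config$bound_width,
                    seed_par + config$bound_width)
  m <- count_matrix(records$sequence)
  out <- with_local_seed(config$rng_seed,
    basin_hop_matrix(seed_par, b$lower, b$upper, m,
                     records$consensus_pi, config))
  out$seed_name <- config$seeds[[1L]]$name
  out$lower <- b$lower
  out$upper <- b$upper
  out
}

#' Cross-validated pKa optimization
#'
#' Splits the dataset into `n_folds` folds; for each fold, basin-hopping is
#' run on the other `n_folds - 1` folds and the held-out fold provides an
#' unbiased cost estimate. The per-fold parameter vectors are averaged
#' (plain arithmetic mean) into the final set.
#'
#' @param config An [optimizer_config()] (its first seed is used).
#' @param records A `pi_dataset` with `consensus_pi` set; at least
#'   `n_folds` records.
#' @return An `optimization_result`: list with `final_set` (a `pka_set`),
#'   `per_fold_pars` (n_folds x 9 matrix), `train_rmsd` (cost of the final
#'   set on the full dataset), `cv_rmsd` (mean held-out-fold cost),
#'   `fold_cv_rmsd`, `traces` and `seed_name`.
#' @export
cross_validated_optimize <- function(config, records) {
  stopifnot(inherits(config, "optimizer_config"),
            inherits(records, "pi_dataset"))
  n <- nrow(records)
  k <- config$n_folds
  if (n < k) stop("fewer records than folds", call. = FALSE)
  if (anyNA(records$consensus_pi)) {
    stop("all records need a consensus_pi", call. = FALSE)
  }
  seed_par <- as_par_vector(config$seeds[[1L]])
  b <- clamp_bounds(seed_par - config$bound_width,
                    seed_par + config$bound_width)
  m <- count_matrix(records$sequence)
  y <- records$consensus_pi
  fold_of <- with_local_seed(config$rng_seed,
                             sample(rep_len(seq_len(k), n)))
  pars <- matrix(NA_real_, nrow = k, ncol = 9L,
                 dimnames = list(NULL, PKA_GROUPS))
  fold_cv <- numeric(k)
  traces <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold_of != f
    out <- with_local_seed(config$rng_seed + f,
      basin_hop_matrix(seed_par, b$lower, b$upper,
                       m[tr, , drop = FALSE], y[tr], config))
    pars[f, ] <- out$par
    fold_cv[f] <- cost_matrix(out$par, m[!tr, , drop = FALSE], y[!tr],
                              config$solver_precision)
    traces[[f]] <- out$trace
  }
  final <- colMeans(pars)
  structure(
    list(final_set = new_pka_set(as.numeric(final), name = "optimized",
                                 provenance = sprintf(
                                   "basin-hopping, %d-fold CV, seed set %s",
                                   k, config$seeds[[1L]]$name)),
         per_fold_pars = pars,
         train_rmsd = cost_matrix(final, m, y, config$solver_precision),
         cv_rmsd = mean(fold_cv),
         fold_cv_rmsd = fold_cv,
         traces = traces,
         seed_name = config$seeds[[1L]]$name),
    class = "optimization_result"
  )
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf(
    "<optimization_result> seed %s; train RMSD %.4f; CV RMSD %.4f\n",
    x$seed_name, x$train_rmsd, x$cv_rmsd))
  print(round(x$final_set$values, 4))
  invisible(x)
}

#' Multi-seed, multi-restart pKa optimization
#'
#' Runs [cross_validated_optimize()] from every seed set in the
#' configuration, `n_restarts` times each with independent RNG streams, and
#' returns the result with the lowest cross-validated RMSD (first winner on
#' ties, so the outcome is deterministic given `rng_seed`).
#'
#' @inheritParams cross_validated_optimize
#' @return The winning `optimization_result`, with `n_runs` attached.
#' @export
multi_seed_optimize <- function(config, records) {
  stopifnot(inherits(config, "optimizer_config"))
  best <- NULL
  run <- 0L
  for (s in seq_along(config$seeds)) {
    for (r in seq_len(config$n_restarts)) {
      run <- run + 1L
      cfg <- config
      cfg$seeds <- config$seeds[s]
      cfg$rng_seed <- (config$rng_seed + 7919L * (run - 1L)) %% .Machine$integer.max
      res <- cross_validated_optimize(cfg, records)
      if (is.null(best) || res$cv_rmsd < best$cv_rmsd) best <- res
    }
  }
  best$n_runs <- run
  best
}
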
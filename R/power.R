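# Six-step simulation procedure for power estimation:
#  1. specify (n, mu, phi, gamma, alpha, T)
#  2. simulate T datasets from BNB under the null (gamma0) and T under the
#     alternative (gamma)
#  3. compute the chosen statistic on every null dataset
#  4. take the 100(1-alpha)th percentile of the null statistics as the
#     critical value (or the chi-square quantile)
#  5. compute the statistic on every alternative dataset
#  6. report the rejection fraction under the alternative

#' Scenario for a power or false-positive-rate run
#'
#' Bundles every input of the simulation procedure. `gamma` is the
#' alternative fold ratio (`gamma = 1` makes the alternative coincide with
#' the null, so estimated power equals the false positive rate).
#'
#' @param n Pairs per dataset.
#' @param mu Baseline mean expression.
#' @param phi Dispersion.
#' @param gamma Alternative fold ratio.
#' @param alpha Nominal false positive rate in (0, 1).
#' @param T Simulations per hypothesis.
#' @param test Test statistic name (see [simulate_null_stats()]).
#' @param critical_source `"empirical"` or `"chi2"`.
#' @param seed Integer seed for the scenario's streams.
#' @param gamma0 Null fold ratio (default 1: power is always computed
#'   against no differential expression, also for fold ratios below 1).
#' @return An object of class `"scenario"`.
#' @export
scenario <- function(n, mu, phi, gamma, alpha, T = 20000L,
                     test = "bnb-lrt",
                     critical_source = c("empirical", "chi2"),
                     seed = 1L, gamma0 = 1) {
  critical_source <- match.arg(critical_source)
  test <- match.arg(test, c(.TESTS, .DIAG_TESTS))
  for (nm in c("n", "mu", "phi", "gamma", "T", "gamma0")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single positive number", nm), call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie in (0, 1)", call. = FALSE)
  structure(list(n = as.integer(n), mu = mu, phi = phi, gamma = gamma,
                 alpha = alpha, T = as.integer(T), test = test,
                 critical_source = critical_source,
                 seed = as.integer(seed), gamma0 = gamma0),
            class = "scenario")
}

#' Estimate power for one scenario
#'
#' Runs the six-step procedure for a single scenario cell: simulates `T`
#' null and `T` alternative datasets from the BNB generator on disjoint
#' derived seed streams, computes the statistic on each, sets the critical
#' value per `critical_source`, and returns the alternative rejection
#' fraction. Rejection requires the statistic to exceed the critical value
#' strictly, the conservative reading of an upper-percentile threshold.
#'
#' @param sc A [scenario()].
#' @param n_nodes Quadrature nodes for GLMM tests.
#' @param null_stats Optionally, a precomputed [null_distribution()] for
#'   this (n, mu, phi, gamma0) cell, to share one null across several
#'   alternatives and alpha levels.
#' @return An object of class `"power_result"`: `power`, `mc_se`,
#'   `critical_value`, failure counts and the scenario.
#' @export
estimate_power <- function(sc, n_nodes = 25L, null_stats = NULL) {
  stopifnot(inherits(sc, "scenario"))
  cell_seed <- derive_seed(sc$seed, "cell", sc$n, sc$mu, sc$phi)
  if (is.null(null_stats)) {
    null_stats <- simulate_null_stats(
      sc$n, sc$mu, sc$phi, sc$test, sc$T,
      seed = derive_seed(cell_seed, "null"),
      gamma0 = sc$gamma0, n_nodes = n_nodes,
      diagnostics = sc$test %in% .DIAG_TESTS)
  }
  crit <- if (sc$critical_source == "empirical")
    critical_value(null_stats, sc$alpha)
  else chi2_critical_value(sc$alpha, df = 1L)
  alt <- simulate_stats(sc$n, sc$mu, sc$gamma, sc$phi, sc$test, sc$T,
                        seed = derive_seed(cell_seed, "alt", sc$gamma),
                        gamma0 = sc$gamma0, n_nodes = n_nodes)
  retained <- length(alt$stats)
  if (retained == 0L) stop("all alternative fits failed", call. = FALSE)
  pow <- mean(alt$stats > crit)
  structure(list(scenario = sc,
                 power = pow,
                 mc_se = sqrt(pow * (1 - pow) / retained),
                 critical_value = crit,
                 n_failed_null = null_stats$n_failed,
                 n_failed_alt = alt$n_failed,
                 n_retained_alt = retained,
                 warning = null_stats$warning),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  sc <- x$scenario
  cat(sprintf(
    "Power %.4f (MC SE %.4f) | %s, %s critical value %.4f\n",
    x$power, x$mc_se, sc$test, sc$critical_source, x$critical_value))
  cat(sprintf(
    "  n=%d mu=%g gamma=%g phi=%g alpha=%g T=%d seed=%d; failed: %d null, %d alt\n",
    sc$n, sc$mu, sc$gamma, sc$phi, sc$alpha, sc$T, sc$seed,
    x$n_failed_null, x$n_failed_alt))
  invisible(x)
}

#' Power over a grid of scenarios
#'
#' Evaluates [estimate_power()] on the cartesian grid of the supplied
#' parameter vectors, sharing one simulated null per (n, mu, phi) cell
#' across all fold ratios and alpha levels, and one simulated alternative
#' per fold ratio across alpha levels. Every cell's seed derives
#' deterministically from `seed`, so results do not depend on evaluation
#' order and re-runs are identical.
#'
#' @param n,mu,phi,gamma,alpha Vectors of grid values. Defaults are the
#'   standard study grid: n = 5..25, mu = 3..100, gamma = 1/3..3,
#'   phi = 0.01..100, four alpha levels.
#' @param test Character vector of tests to run.
#' @param critical_source `"empirical"` or `"chi2"`.
#' @param T Simulations per hypothesis per cell.
#' @param seed Master seed.
#' @param n_nodes Quadrature nodes for GLMM tests.
#' @param verbose Print one line per cell as it completes.
#' @return A long-format `data.frame`, one row per
#'   (test, n, mu, phi, gamma, alpha) cell with power, MC standard error,
#'   critical value, failure counts and the cell seed.
#' @export
power_grid <- function(n = c(5L, 10L, 15L, 20L, 25L),
                       mu = c(3, 5, 10, 20, 100),
                       phi = c(0.01, 0.1, 1, 10, 100),
                       gamma = c(1 / 3, 1 / 2, 1, 2, 3),
                       alpha = c(0.01, 0.005, 0.001, 0.0005),
                       test = "bnb-lrt",
                       critical_source = "empirical",
                       T = 20000L, seed = 1L, n_nodes = 25L,
                       verbose = FALSE) {
  cells <- expand.grid(test = test, n = n, mu = mu, phi = phi,
                       stringsAsFactors = FALSE)
  if (nrow(cells) == 0L || length(gamma) == 0L || length(alpha) == 0L)
    stop("empty grid", call. = FALSE)
  out <- vector("list", nrow(cells) * length(gamma) * length(alpha))
  k <- 0L
  for (i in seq_len(nrow(cells))) {
    ci <- cells[i, ]
    cell_seed <- derive_seed(seed, "cell", ci$n, ci$mu, ci$phi)
    nd <- simulate_null_stats(ci$n, ci$mu, ci$phi, ci$test, T,
                              seed = derive_seed(cell_seed, "null"),
                              n_nodes = n_nodes)
    for (g in gamma) {
      sims <- simulate_stats(ci$n, ci$mu, g, ci$phi, ci$test, T,
                             seed = derive_seed(cell_seed, "alt", g),
                             n_nodes = n_nodes)
      retained <- length(sims$stats)
      for (a in alpha) {
        crit <- if (critical_source == "empirical")
          critical_value(nd, a)
        else chi2_critical_value(a, df = 1L)
        pow <- mean(sims$stats > crit)
        k <- k + 1L
        out[[k]] <- data.frame(
          test = ci$test, n = ci$n, mu = ci$mu, phi = ci$phi,
          gamma = g, alpha = a, critical_source = critical_source,
          critical_value = crit, power = pow,
          mc_se = sqrt(pow * (1 - pow) / retained),
          n_failed_null = nd$n_failed, n_failed_alt = sims$n_failed,
          cell_seed = cell_seed, T = T,
          stringsAsFactors = FALSE)
        if (verbose)
          cat(sprintf(
            "%s n=%d mu=%g phi=%g gamma=%g alpha=%g -> power %.4f\n",
            ci$test, ci$n, ci$mu, ci$phi, g, a, pow))
      }
    }
  }
  do.call(rbind, out)
}

#' Smallest sample size reaching a target power
#'
#' Walks `n_range` in ascending order, estimating power at each sample size,
#' and returns the first n whose estimated power reaches `target_power`.
#' The whole power curve is returned either way; if no n qualifies, `n` is
#' `NA` and the curve shows how far the search got.
#'
#' @param mu,phi,gamma,alpha Scenario parameters (see [scenario()]).
#' @param target_power Required power in [0, 1].
#' @param test Test statistic name.
#' @param critical_source `"empirical"` or `"chi2"`.
#' @param n_range Candidate sample sizes, default 3:20.
#' @param T Simulations per hypothesis per sample size.
#' @param seed Master seed.
#' @param n_nodes Quadrature nodes for GLMM tests.
#' @return An object of class `"sample_size_result"`: `n` (or `NA`),
#'   `target_power` and `curve` (a `data.frame` of n vs power).
#' @export
sample_size_for_power <- function(mu, phi, gamma, alpha, target_power,
                                  test = "bnb-lrt",
                                  critical_source = "empirical",
                                  n_range = 3:20, T = 20000L, seed = 1L,
                                  n_nodes = 25L) {
  if (length(n_range) == 0L) stop("'n_range' is empty", call. = FALSE)
  if (target_power < 0 || target_power > 1)
    stop("'target_power' must lie in [0, 1]", call. = FALSE)
  n_range <- sort(unique(as.integer(n_range)))
  rows <- list()
  found <- NA_integer_
  for (n in n_range) {
    pr <- estimate_power(scenario(n, mu, phi, gamma, alpha, T = T,
                                  test = test,
                                  critical_source = critical_source,
                                  seed = seed),
                         n_nodes = n_nodes)
    rows[[length(rows) + 1L]] <- data.frame(
      n = n, power = pr$power, mc_se = pr$mc_se,
      critical_value = pr$critical_value)
    if (pr$power >= target_power) { found <- n; break }
  }
  structure(list(n = found, target_power = target_power,
                 mu = mu, phi = phi, gamma = gamma, alpha = alpha,
                 test = test, critical_source = critical_source,
                 T = T, seed = seed,
                 curve = do.call(rbind, rows)),
            class = "sample_size_result")
}

#' @export
print.sample_size_result <- function(x, ...) {
  if (is.na(x$n)) {
    cat(sprintf(
      "No sample size in range reached power %.2f (largest tried: n=%d, power %.4f)\n",
      x$target_power, max(x$curve$n), x$curve$power[nrow(x$curve)]))
  } else {
    cat(sprintf(
      "n = %d pairs per condition reaches power %.2f (estimated %.4f)\n",
      x$n, x$target_power, x$curve$power[nrow(x$curve)]))
  }
  cat(sprintf("  mu=%g phi=%g gamma=%g alpha=%g, %s (%s critical values), T=%d\n",
              x$mu, x$phi, x$gamma, x$alpha, x$test, x$critical_source, x$T))
  invisible(x)
}
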
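# The empirical parametric test: simulate the null distribution of a test
# statistic under BNB(mu, gamma0, phi), take its upper percentile as the
# critical value, and evaluate false positive rates against either that
# empirical critical value or the asymptotic chi-square(1) quantile.

.TESTS <- c("bnb-lrt", "bnb-wald", "poisson-lmm-lrt", "nb-lmm-lrt")
.DIAG_TESTS <- c("poisson-lmm-wald", "nb-lmm-wald")

# Compute one test statistic on one paired dataset. Returns a scalar;
# errors propagate to the caller (the simulation loop counts them).
compute_stat <- function(data, test, gamma0 = 1, n_nodes = 25L) {
  switch(test,
    "bnb-lrt" = bnb_lrt(data, gamma0 = gamma0),
    "bnb-wald" = bnb_wald(data, gamma0 = gamma0),
    "poisson-lmm-lrt" = as.numeric(
      glmm_lrt(data, "poisson", beta1_null = log(gamma0),
               n_nodes = n_nodes)),
    "nb-lmm-lrt" = as.numeric(
      glmm_lrt(data, "negative_binomial", beta1_null = log(gamma0),
               n_nodes = n_nodes)),
    "poisson-lmm-wald" = glmm_wald(data, "poisson",
                                   beta1_null = log(gamma0),
                                   n_nodes = n_nodes, diagnostics = TRUE),
    "nb-lmm-wald" = glmm_wald(data, "negative_binomial",
                              beta1_null = log(gamma0),
                              n_nodes = n_nodes, diagnostics = TRUE),
    stop(sprintf("unknown test '%s'", test), call. = FALSE))
}

# Simulate T datasets from BNB(mu, gamma, phi) with n pairs each and compute
# the statistic on every one. Returns stats (retained), failure count and
# the count of negative (NB-LMM) statistics.
simulate_stats <- function(n, mu, gamma, phi, test, T, seed, gamma0 = 1,
                           n_nodes = 25L) {
  set.seed(seed)
  params <- bnb_params(mu, gamma, phi)
  stats <- numeric(T)
  failed <- 0L
  for (t in seq_len(T)) {
    d <- bnb_rvs(params, n)
    s <- tryCatch(compute_stat(d, test, gamma0 = gamma0, n_nodes = n_nodes),
                  error = function(e) NA_real_)
    stats[t] <- s
    if (is.na(s)) failed <- failed + 1L
  }
  list(stats = stats[!is.na(stats)], n_failed = failed,
       n_negative = sum(stats < 0, na.rm = TRUE))
}

#' Null distribution of a test statistic
#'
#' Container for a bag of simulated null statistics together with its
#' generating scenario; [critical_value()] extracts upper percentiles from
#' it. Usually produced by [simulate_null_stats()], but can be built
#' directly from a numeric vector.
#'
#' @param stats Numeric vector of null statistics.
#' @param scenario Optional list describing the generating scenario.
#' @param T Number of attempted simulations (default `length(stats)`).
#' @param n_failed Number of excluded non-convergent fits.
#' @param seed Seed used to generate the statistics, if any.
#' @return An object of class `"null_distribution"`.
#' @export
null_distribution <- function(stats, scenario = NULL, T = length(stats),
                              n_failed = 0L, seed = NA_integer_) {
  stats <- as.numeric(stats)
  if (anyNA(stats)) stop("'stats' must not contain NA", call. = FALSE)
  if (length(stats) + n_failed != T)
    stop("length(stats) + n_failed must equal T", call. = FALSE)
  warn <- if (n_failed > 0.01 * T)
    sprintf("%.1f%% of simulated fits failed (> 1%%)", 100 * n_failed / T)
  else NULL
  structure(list(stats = stats, sorted = sort(stats), scenario = scenario,
                 T = T, n_failed = n_failed, seed = seed,
                 n_negative = sum(stats < 0), warning = warn),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("Empirical null distribution: %d statistics (%d failed fits%s)\n",
              length(x$stats), x$n_failed,
              if (x$n_negative > 0)
                sprintf(", %d negative", x$n_negative) else ""))
  if (!is.null(x$scenario))
    cat("  scenario:", paste(names(x$scenario), unlist(x$scenario),
                             sep = "=", collapse = ", "), "\n")
  if (!is.null(x$warning)) cat("  warning:", x$warning, "\n")
  invisible(x)
}

#' Simulate the empirical null distribution of a test statistic
#'
#' Draws `T` datasets from BNB(mu, gamma0, phi) with `n` pairs each,
#' computes the chosen statistic on every dataset, and returns the retained
#' statistics as a [null_distribution()]. Non-convergent fits are counted
#' and excluded, never imputed; a failure fraction above 1% is recorded as a
#' run-level warning in the result.
#'
#' @param n Pairs per dataset.
#' @param mu Baseline mean expression.
#' @param phi Dispersion.
#' @param test One of `"bnb-lrt"`, `"bnb-wald"`, `"poisson-lmm-lrt"`,
#'   `"nb-lmm-lrt"`; the unstable GLMM Wald statistics additionally require
#'   `diagnostics = TRUE`.
#' @param T Number of simulations (>= 100).
#' @param seed Integer seed for the stream.
#' @param gamma0 Null fold ratio (default 1).
#' @param n_nodes Quadrature nodes for the GLMM tests.
#' @param diagnostics Set `TRUE` to allow the GLMM Wald statistics.
#' @return A [null_distribution()].
#' @export
simulate_null_stats <- function(n, mu, phi, test, T, seed, gamma0 = 1,
                                n_nodes = 25L, diagnostics = FALSE) {
  test <- match.arg(test, c(.TESTS, .DIAG_TESTS))
  if (test %in% .DIAG_TESTS && !isTRUE(diagnostics))
    stop("GLMM Wald statistics require diagnostics = TRUE", call. = FALSE)
  if (T < 100) stop("'T' must be at least 100", call. = FALSE)
  sim <- simulate_stats(n, mu, gamma0, phi, test, T, seed, gamma0 = gamma0,
                        n_nodes = n_nodes)
  null_distribution(sim$stats,
                    scenario = list(n = n, mu = mu, phi = phi,
                                    gamma0 = gamma0, test = test),
                    T = T, n_failed = sim$n_failed, seed = seed)
}

#' Empirical critical value at nominal level alpha
#'
#' The 100(1 - alpha)th percentile of the retained null statistics, using
#' the linear-interpolation sample percentile that places the k-th order
#' statistic at probability (k - 1)/(N - 1).
#'
#' @param nd A [null_distribution()].
#' @param alpha Nominal false positive rate, in (0, 1); vectorized.
#' @return Critical value(s), non-increasing in `alpha`.
#' @examples
#' critical_value(null_distribution(1:10), 0.1)  # 9.1
#' @export
critical_value <- function(nd, alpha) {
  stopifnot(inherits(nd, "null_distribution"))
  if (any(alpha <= 0 | alpha >= 1))
    stop("'alpha' must lie in (0, 1)", call. = FALSE)
  if (length(nd$stats) < 1 / min(alpha))
    warning(sprintf(
      "only %d statistics for alpha = %g; the percentile is extrapolated",
      length(nd$stats), min(alpha)))
  unname(stats::quantile(nd$sorted, probs = 1 - alpha, type = 7L))
}

#' Asymptotic chi-square critical value
#'
#' Upper-alpha quantile of the chi-square distribution with `df` degrees of
#' freedom, the reference the LRT statistics are compared against.
#'
#' @param alpha Nominal false positive rate in (0, 1); vectorized.
#' @param df Degrees of freedom (default 1).
#' @return Quantile(s).
#' @examples
#' chi2_critical_value(0.001)  # 10.8276
#' @export
chi2_critical_value <- function(alpha, df = 1L) {
  if (any(alpha <= 0 | alpha >= 1))
    stop("'alpha' must lie in (0, 1)", call. = FALSE)
  if (df < 1) stop("'df' must be a positive integer", call. = FALSE)
  stats::qchisq(1 - alpha, df = df)
}

#' Actual false positive rate of a test
#'
#' Simulates null data and reports the fraction of statistics exceeding the
#' critical value. With `critical_source = "chi2"` the asymptotic
#' chi-square(1) quantile is used. With `"empirical"` the critical value is
#' first extracted from one simulated null replication and then evaluated on
#' an independent second replication (fresh derived seed), so the reported
#' rate is not circular.
#'
#' @inheritParams simulate_null_stats
#' @param alpha Nominal false positive rate.
#' @param critical_source `"empirical"` or `"chi2"`.
#' @return An object of class `"fpr_result"`: fields `fpr`, `mc_se`,
#'   `critical_value`, `critical_source`, `alpha`, `n_failed`, `T`, `seed`,
#'   and the scenario parameters.
#' @export
false_positive_rate <- function(n, mu, phi, test, alpha, T, seed,
                                critical_source = c("empirical", "chi2"),
                                gamma0 = 1, n_nodes = 25L,
                                diagnostics = FALSE) {
  critical_source <- match.arg(critical_source)
  test <- match.arg(test, c(.TESTS, .DIAG_TESTS))
  if (test %in% .DIAG_TESTS && !isTRUE(diagnostics))
    stop("GLMM Wald statistics require diagnostics = TRUE", call. = FALSE)
  if (critical_source == "empirical") {
    nd <- simulate_null_stats(n, mu, phi, test, T,
                              seed = derive_seed(seed, "null-crit"),
                              gamma0 = gamma0, n_nodes = n_nodes,
                              diagnostics = diagnostics)
    crit <- critical_value(nd, alpha)
    n_failed_crit <- nd$n_failed
  } else {
    crit <- chi2_critical_value(alpha, df = 1L)
    n_failed_crit <- 0L
  }
  ev <- simulate_stats(n, mu, gamma0, phi, test, T,
                       seed = derive_seed(seed, "null-eval"),
                       gamma0 = gamma0, n_nodes = n_nodes)
  retained <- length(ev$stats)
  fpr <- mean(ev$stats > crit)
  structure(list(fpr = fpr,
                 mc_se = sqrt(fpr * (1 - fpr) / retained),
                 critical_value = crit,
                 critical_source = critical_source,
                 alpha = alpha, n = n, mu = mu, phi = phi, gamma0 = gamma0,
                 test = test, T = T, seed = seed,
                 n_failed_crit = n_failed_crit,
                 n_failed_eval = ev$n_failed,
                 n_retained = retained),
            class = "fpr_result")
}

#' @export
print.fpr_result <- function(x, ...) {
  cat(sprintf(
    "FPR %.5f (MC SE %.5f) for %s at alpha %g [%s critical value %.4f]\n",
    x$fpr, x$mc_se, x$test, x$alpha, x$critical_source, x$critical_value))
  cat(sprintf("  scenario n=%d mu=%g phi=%g, T=%d, failed fits: %d (crit) %d (eval)\n",
              x$n, x$mu, x$phi, x$T, x$n_failed_crit, x$n_failed_eval))
  invisible(x)
}

#' QQ table of null statistics against the chi-square distribution
#'
#' Pairs the i-th order statistic with the chi-square quantile at
#' probability (i - 0.5)/N, the standard plotting positions for a QQ plot of
#' simulated null statistics against their asymptotic reference.
#'
#' @param nd A [null_distribution()].
#' @param df Chi-square degrees of freedom (default 1).
#' @return A `data.frame` with columns `theoretical` and `empirical`.
#' @export
qq_data <- function(nd, df = 1L) {
  stopifnot(inherits(nd, "null_distribution"))
  N <- length(nd$stats)
  if (N == 0L) stop("empty null distribution", call. = FALSE)
  p <- (seq_len(N) - 0.5) / N
  data.frame(theoretical = stats::qchisq(p, df = df),
             empirical = nd$sorted)
}
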
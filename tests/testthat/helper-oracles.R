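# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: brute-force grid summation for the pmf,
# trapezoid integration for the mixed-model marginal likelihood, profile
# grid search for the fold-ratio MLE.

# Brute-force joint pmf mass over a rectangular grid
bnb_grid_mass <- function(params, xmax, ymax) {
  g <- expand.grid(x = 0:xmax, y = 0:ymax)
  sum(exp(bnb_logpmf(g$x, g$y, params)))
}

# Marginal P(X = x) by summing the joint pmf over y
bnb_marginal_x <- function(x, params, ymax = 500) {
  vapply(x, function(xx)
    sum(exp(bnb_logpmf(rep(xx, ymax + 1), 0:ymax, params))), numeric(1))
}

# Trapezoid-rule marginal log-likelihood for a single-subject GLMM
glmm_loglik_trapezoid <- function(counts, conditions, spec,
                                  lim = 12, n_grid = 200001) {
  b <- seq(-lim, lim, length.out = n_grid)
  lp <- vapply(b, function(bb) {
    eta <- spec$beta0 + spec$beta1 * conditions + bb
    lf <- if (is.null(spec$phi)) sum(dpois(counts, exp(eta), log = TRUE))
    else sum(dnbinom(counts, size = 1 / spec$phi, mu = exp(eta), log = TRUE))
    lf + dnorm(bb, 0, sqrt(spec$sigma2), log = TRUE)
  }, numeric(1))
  m <- max(lp)
  m + log(sum(exp(lp - m)) * (b[2] - b[1]))
}

# Profile log-likelihood over a gamma grid (mu, phi re-maximized per point)
bnb_profile_gamma <- function(data, gammas) {
  vapply(gammas, function(g) bnb_fit(data, gamma_fixed = g)$loglik,
         numeric(1))
}

# Poisson fixed-effects GLM log-likelihood for paired long data
glm_pois_loglik <- function(data, beta0, beta1) {
  eta <- beta0 + beta1 * data$condition + data$offset
  sum(dpois(data$count, exp(eta), log = TRUE))
}
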
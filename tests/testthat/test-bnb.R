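# Bivariate negative binomial: pmf, sampling, fitting, LRT, Wald.

test_that("log-pmf matches the closed collapse at (0,0) and is a proper pmf", {
  # at x = y = 0 the pmf collapses to (1 + phi*mu*(1+gamma))^(-1/phi)
  expect_equal(bnb_logpmf(0, 0, bnb_params(1, 1, 1)), log(1 / 3),
               tolerance = 1e-12)
  expect_equal(bnb_logpmf(0, 0, bnb_params(2, 3, 0.5)),
               -2 * log(1 + 0.5 * 2 * 4), tolerance = 1e-12)

  # total mass 1 over a generous grid, across the parameter ranges the
  # power grid spans
  settings <- list(c(5, 2, 0.5), c(3, 1, 1), c(10, 1 / 3, 0.1),
                   c(1, 3, 2), c(20, 0.5, 0.01))
  for (s in settings) {
    p <- bnb_params(s[1], s[2], s[3])
    span <- ceiling(50 + 10 * p$mu * (1 + p$gamma) * (1 + p$phi))
    expect_equal(bnb_grid_mass(p, span, span), 1, tolerance = 1e-6)
  }
})

test_that("X-marginal equals the negative binomial law", {
  p <- bnb_params(3, 1, 1)
  marg <- bnb_marginal_x(0:20, p)
  expect_equal(marg, dnbinom(0:20, size = 1, mu = 3), tolerance = 1e-8)
  # and exp(logpmf) always lies in (0, 1]
  expect_true(all(exp(bnb_logpmf(0:50, 0:50, p)) <= 1))
})

test_that("pmf and sampler reject invalid input", {
  expect_error(bnb_params(-1, 1, 1), "positive")
  expect_error(bnb_params(1, 0, 1), "positive")
  expect_error(bnb_logpmf(-1, 0, bnb_params(1, 1, 1)), "non-negative")
  expect_error(bnb_logpmf(0.5, 0, bnb_params(1, 1, 1)), "non-negative")
  expect_error(paired_counts(c(1, 2), c(1, 2, 3)), "equal length")
  expect_error(bnb_rvs(bnb_params(1, 1, 1), 0), "positive integer")
})

test_that("sampler moments match the compound-model law", {
  d <- bnb_rvs(bnb_params(10, 2, 1), 1e5, seed = 101)
  # E[X] = mu
  expect_lt(abs(mean(d$x) - 10), 3 * sd(d$x) / sqrt(d$n))
  # Var[X] = mu + phi mu^2 = 110
  v <- var(d$x)
  se_v <- sqrt((mean((d$x - mean(d$x))^4) - v^2) / d$n)
  expect_lt(abs(v - 110), 3 * se_v)
  # Cov[X, Y] = gamma phi mu^2 = 200
  cv <- cov(d$x, d$y)
  xc <- d$x - mean(d$x); yc <- d$y - mean(d$y)
  se_cv <- sqrt((mean(xc^2 * yc^2) - cv^2) / d$n)
  expect_lt(abs(cv - 200), 3 * se_cv)
  # reproducibility: same seed, identical draw
  d2 <- bnb_rvs(bnb_params(10, 2, 1), 1e5, seed = 101)
  expect_identical(d$x, d2$x)
  expect_identical(d$y, d2$y)
})

test_that("fitted fold ratio equals the closed-form MLE sum(y)/sum(x)", {
  set.seed(202)
  for (i in 1:50) {
    p <- bnb_params(runif(1, 1, 40), exp(runif(1, -1, 1)),
                    exp(runif(1, -3, 1)))
    d <- bnb_rvs(p, sample(5:30, 1))
    if (sum(d$x) == 0 || sum(d$y) == 0) next
    fit <- bnb_fit(d)
    expect_true(fit$converged)
    expect_equal(fit$params$gamma, sum(d$y) / sum(d$x), tolerance = 1e-6)
  }
})

test_that("fold-ratio MLE is confirmed by independent profile grid search", {
  d <- bnb_rvs(bnb_params(8, 1.7, 0.8), 15, seed = 33)
  ghat <- sum(d$y) / sum(d$x)
  gammas <- ghat * exp(seq(-0.5, 0.5, length.out = 41))
  prof <- bnb_profile_gamma(d, gammas)
  expect_equal(gammas[which.max(prof)], ghat, tolerance = 0.03)
  expect_lte(max(prof), bnb_fit(d)$loglik + 1e-6)
})

test_that("parameters are recovered from a large sample", {
  d <- bnb_rvs(bnb_params(10, 2, 1), 1e4, seed = 7)
  fit <- bnb_fit(d)
  expect_equal(fit$params$mu, 10, tolerance = 0.05)
  expect_equal(fit$params$gamma, 2, tolerance = 0.05)
  expect_equal(fit$params$phi, 1, tolerance = 0.05)
})

test_that("constrained fit at the unconstrained MLE matches the full fit", {
  d <- paired_counts(c(3, 5), c(6, 10))   # sum(y)/sum(x) = 2 exactly
  full <- bnb_fit(d)
  con <- bnb_fit(d, gamma_fixed = 2)
  expect_equal(con$loglik, full$loglik, tolerance = 1e-8)
  expect_equal(bnb_lrt(d, gamma0 = 2), 0, tolerance = 1e-6)
})

test_that("degenerate datasets are handled as specified", {
  expect_error(bnb_fit(paired_counts(c(0, 0), c(0, 0))), "not identifiable")
  d <- paired_counts(c(4, 7, 2), c(0, 0, 0))   # sum(y) = 0
  fit <- bnb_fit(d)
  expect_true(fit$boundary_flag)
  expect_lt(fit$params$gamma, 1e-10)
  expect_error(bnb_wald(d), "boundary|unavailable")
})

test_that("LRT is invariant to subject permutation and non-negative", {
  d <- bnb_rvs(bnb_params(6, 1.4, 0.6), 12, seed = 9)
  s1 <- bnb_lrt(d)
  perm <- sample(d$n)
  s2 <- bnb_lrt(paired_counts(d$x[perm], d$y[perm]))
  expect_equal(s1, s2, tolerance = 1e-6)
  expect_gte(s1, 0)
})

test_that("null LRT statistics are calibrated against chi-square(1)", {
  set.seed(404)
  p <- bnb_params(10, 1, 1)
  stats <- vapply(1:2000, function(i) bnb_lrt(bnb_rvs(p, 10)), numeric(1))
  expect_gte(min(stats), 0)
  # mean of a chi2(1) is 1
  expect_lt(abs(mean(stats) - 1), 3 * sd(stats) / sqrt(2000))
  ks <- suppressWarnings(ks.test(stats, pchisq, df = 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("Wald statistic is zero at the null MLE and tracks the observed
          information", {
  d <- paired_counts(c(3, 5, 4), c(5, 4, 3))  # sum(y)/sum(x) = 1
  expect_equal(bnb_wald(d, gamma0 = 1), 0, tolerance = 1e-8)

  # the estimated variance of log(gamma_hat) matches the spread of
  # log(gamma_hat) across replicate simulations
  set.seed(55)
  p <- bnb_params(10, 2, 1)
  R <- 800; n <- 2000
  lg <- numeric(R); vhat <- numeric(R)
  for (r in 1:R) {
    d <- bnb_rvs(p, n)
    fit <- bnb_fit(d)
    lg[r] <- log(fit$params$gamma)
    w <- bnb_wald(d, gamma0 = 2)
    vhat[r] <- (lg[r] - log(2))^2 / max(w, 1e-300)
  }
  expect_equal(median(vhat), var(lg), tolerance = 0.10)
})
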
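# Random-intercept count GLMMs: quadrature, fitting, LRT.

test_that("spec and data containers validate input", {
  expect_error(glmm_spec(0, 0, -1), "non-negative")
  expect_error(glmm_spec(0, 0, 1, phi = -2), "positive")
  expect_identical(glmm_spec(0, 0, 1)$family, "poisson")
  expect_identical(glmm_spec(0, 0, 1, phi = 0.5)$family, "negative_binomial")
  expect_error(long_counts(1:2, c(0, 2), c(1, 1)), "0/1")
  d <- paired_to_long(paired_counts(c(1, 2), c(3, 4)))
  expect_identical(nrow(d), 4L)
  expect_identical(d$count[d$subject == 2 & d$condition == 1], 4)
})

test_that("marginal likelihood with sigma2 = 0 equals the GLM likelihood", {
  d <- glmm_simulate(glmm_spec(1.2, 0.4, 0), 15, seed = 21)
  sp <- glmm_spec(1.2, 0.4, 0)
  expect_equal(glmm_marginal_loglik(d, sp),
               glm_pois_loglik(d, 1.2, 0.4), tolerance = 1e-6)
  spn <- glmm_spec(1.2, 0.4, 0, phi = 0.7)
  eta <- 1.2 + 0.4 * d$condition
  expect_equal(glmm_marginal_loglik(d, spn),
               sum(dnbinom(d$count, size = 1 / 0.7, mu = exp(eta),
                           log = TRUE)),
               tolerance = 1e-6)
})

test_that("quadrature agrees with brute-force integration and is node-stable", {
  # single subject, counts (2, 3): 1-D trapezoid oracle
  d1 <- long_counts(c(1, 1), c(0, 1), c(2, 3))
  sp <- glmm_spec(0.5, 0.3, 0.8)
  expect_equal(glmm_marginal_loglik(d1, sp, n_nodes = 25),
               glmm_loglik_trapezoid(c(2, 3), c(0, 1), sp),
               tolerance = 1e-8)
  spn <- glmm_spec(0.5, 0.3, 0.8, phi = 0.5)
  expect_equal(glmm_marginal_loglik(d1, spn, n_nodes = 25),
               glmm_loglik_trapezoid(c(2, 3), c(0, 1), spn),
               tolerance = 1e-8)

  # node-count stability on a 10-subject fixture
  d <- glmm_simulate(glmm_spec(1.5, 0.6, 0.9), 10, seed = 8)
  sp2 <- glmm_spec(1.4, 0.5, 0.7)
  expect_lt(abs(glmm_marginal_loglik(d, sp2, 25) -
                glmm_marginal_loglik(d, sp2, 51)), 1e-6)
  sp3 <- glmm_spec(1.4, 0.5, 0.7, phi = 0.3)
  expect_lt(abs(glmm_marginal_loglik(d, sp3, 25) -
                glmm_marginal_loglik(d, sp3, 51)), 1e-6)
})

test_that("fit agrees with an independent mixed-model implementation", {
  skip_if_not_installed("lme4")
  d <- glmm_simulate(glmm_spec(2, 0.7, 0.5), 30, seed = 7)
  m <- lme4::glmer(count ~ condition + (1 | subject), data = d,
                   family = stats::poisson, nAGQ = 25)
  fit <- glmm_fit(d, "poisson")
  expect_equal(fit$spec$beta0, unname(lme4::fixef(m)[1]), tolerance = 1e-4)
  expect_equal(fit$spec$beta1, unname(lme4::fixef(m)[2]), tolerance = 1e-4)
  expect_equal(fit$spec$sigma2,
               unname(as.numeric(lme4::VarCorr(m)$subject)),
               tolerance = 1e-3)
})

test_that("simulator moments follow the log-normal mixing law", {
  d0 <- glmm_simulate(glmm_spec(1, 0.5, 0), 1e5, seed = 31)
  m0 <- mean(d0$count[d0$condition == 0])
  expect_lt(abs(m0 - exp(1)), 3 * sqrt(exp(1) / 1e5))
  # marginal mean exp(beta0 + sigma2/2) under a normal random intercept
  d1 <- glmm_simulate(glmm_spec(1, 0, 1), 1e5, seed = 32)
  x0 <- d1$count[d1$condition == 0]
  expect_lt(abs(mean(x0) - exp(1.5)), 3 * sd(x0) / sqrt(1e5))
  # shared intercept induces positive within-subject correlation
  x <- d1$count[d1$condition == 0][order(d1$subject[d1$condition == 0])]
  y <- d1$count[d1$condition == 1][order(d1$subject[d1$condition == 1])]
  expect_gt(cor(x, y), 0.2)
  expect_identical(glmm_simulate(glmm_spec(1, 0, 1), 50, seed = 5)$count,
                   glmm_simulate(glmm_spec(1, 0, 1), 50, seed = 5)$count)
})

test_that("Poisson-LMM recovers the fold ratio from BNB-generated data", {
  d <- bnb_rvs(bnb_params(10, 2, 1), 200, seed = 77)
  fit <- glmm_fit(d, "poisson")
  expect_true(fit$converged)
  expect_equal(exp(fit$spec$beta1), 2, tolerance = 0.1)
})

test_that("constraining beta1 at the MLE reproduces the full fit", {
  d <- bnb_rvs(bnb_params(8, 1.5, 0.5), 25, seed = 13)
  full <- glmm_fit(d, "poisson")
  con <- glmm_fit(d, "poisson", beta1_fixed = full$spec$beta1)
  expect_equal(con$loglik, full$loglik, tolerance = 1e-6)
  expect_lt(abs(glmm_lrt(d, "poisson", beta1_null = full$spec$beta1)), 1e-4)
})

test_that("sigma2 = 0 data drive the variance to the boundary, matching the GLM", {
  d <- glmm_simulate(glmm_spec(2, 0.3, 0), 40, seed = 19)
  fit <- glmm_fit(d, "poisson")
  expect_true(fit$boundary_flag)
  glm_ml <- stats::optim(c(2, 0.3),
                         function(b) -glm_pois_loglik(d, b[1], b[2]),
                         method = "BFGS")
  expect_equal(fit$loglik, -glm_ml$value, tolerance = 1e-6)
})

test_that("Poisson-LMM null LRTs are non-negative and chi-square-like", {
  set.seed(606)
  p <- bnb_params(10, 1, 1)
  stats <- vapply(1:200, function(i)
    glmm_lrt(bnb_rvs(p, 10), "poisson"), numeric(1))
  expect_gte(min(stats), 0)
  expect_lt(abs(mean(stats) - 1), 4 * sd(stats) / sqrt(200))
})

test_that("GLMM Wald statistics stay behind the diagnostics flag", {
  d <- bnb_rvs(bnb_params(10, 1, 1), 10, seed = 3)
  expect_error(glmm_wald(d, "poisson"), "diagnostics")
  w <- glmm_wald(d, "poisson", diagnostics = TRUE)
  expect_gte(w, 0)
})
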
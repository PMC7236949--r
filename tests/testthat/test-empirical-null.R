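# Empirical null distributions, critical values, FPR, QQ tables.

test_that("empirical percentile follows the stated interpolation convention", {
  nd <- null_distribution(1:10)
  expect_equal(critical_value(nd, 0.1), 9.1)
  sym <- null_distribution(-5:5)
  expect_equal(critical_value(sym, 0.5), 0)
  # monotone non-increasing in alpha
  alphas <- c(0.001, 0.01, 0.05, 0.2, 0.5)
  cv <- suppressWarnings(critical_value(null_distribution(rchisq(500, 1)),
                                        alphas))
  expect_true(all(diff(cv) <= 0))
  expect_error(critical_value(nd, 1.2), "0, 1")
  expect_warning(critical_value(nd, 0.01), "extrapolated")
})

test_that("large-sample empirical percentile recovers the chi-square quantile", {
  set.seed(88)
  nd <- null_distribution(rchisq(1e5, df = 1))
  q <- critical_value(nd, 0.001)
  # order-statistic MC error: sqrt(a(1-a)/T) / f(q) ~ 0.33 at this quantile
  expect_lt(abs(q - qchisq(0.999, 1)), 1)
})

test_that("chi-square critical values invert the chi-square CDF", {
  expect_equal(chi2_critical_value(0.001), 10.8276, tolerance = 1e-3)
  expect_equal(chi2_critical_value(0.5), 0.4549, tolerance = 1e-3)
  a <- c(0.0005, 0.001, 0.005, 0.01, 0.05)
  expect_true(all(diff(chi2_critical_value(a)) < 0))
  expect_error(chi2_critical_value(0), "0, 1")
  # oracle: numerical inversion of the CDF
  expect_equal(pchisq(chi2_critical_value(0.013), 1), 1 - 0.013,
               tolerance = 1e-10)
})

test_that("null distribution accounting is exact and reproducible", {
  expect_error(null_distribution(1:5, T = 7, n_failed = 1), "must equal")
  nd <- null_distribution(1:98, T = 100, n_failed = 2)
  expect_match(nd$warning, "failed")
  a <- simulate_null_stats(8, 5, 1, "bnb-lrt", 200, seed = 42)
  b <- simulate_null_stats(8, 5, 1, "bnb-lrt", 200, seed = 42)
  expect_identical(a$stats, b$stats)
  expect_identical(length(a$stats) + a$n_failed, 200L)
  expect_error(simulate_null_stats(8, 5, 1, "bnb-lrt", 50, seed = 1),
               "at least 100")
  expect_error(simulate_null_stats(8, 5, 1, "nb-lmm-wald", 200, seed = 1),
               "diagnostics")
})

test_that("QQ tables use (i - 0.5)/N plotting positions", {
  nd1 <- null_distribution(3.2)
  qq1 <- qq_data(nd1)
  expect_equal(qq1$theoretical, qchisq(0.5, 1))
  expect_equal(qq1$empirical, 3.2)
  expect_error(qq_data(null_distribution(numeric(0))), "empty")

  set.seed(12)
  qq <- qq_data(null_distribution(rchisq(20000, 1)))
  slope <- sum(qq$theoretical * qq$empirical) / sum(qq$theoretical^2)
  expect_gt(slope, 0.95)
  expect_lt(slope, 1.05)
})

test_that("the empirical parametric test controls the FPR on an independent
          replication", {
  r <- false_positive_rate(10, 10, 1, "bnb-lrt", alpha = 0.01, T = 2000,
                           seed = 5, critical_source = "empirical")
  expect_lt(abs(r$fpr - 0.01), 3 * sqrt(0.01 * 0.99 / 2000))
  # the two replications really are different draws
  expect_false(identical(derive_seed(5, "null-crit"),
                         derive_seed(5, "null-eval")))
})

test_that("seed derivation separates streams and stays in integer range", {
  s1 <- derive_seed(1, "cell", 5, 14, 1, "bnb-lrt")
  s2 <- derive_seed(1, "cell", 5, 14, 1, "bnb-wald")
  s3 <- derive_seed(2, "cell", 5, 14, 1, "bnb-lrt")
  expect_true(s1 != s2 && s1 != s3)
  expect_identical(s1, derive_seed(1, "cell", 5, 14, 1, "bnb-lrt"))
  seeds <- vapply(1:500, function(i) derive_seed(i, "x"), integer(1))
  expect_true(all(seeds >= 1 & seeds <= 2147483646))
})
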
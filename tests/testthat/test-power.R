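# Six-step power procedure, grids, sample-size search.

test_that("scenario validates its inputs", {
  expect_error(scenario(0, 10, 1, 2, 0.01), "positive")
  expect_error(scenario(5, 10, 1, 2, 1.5), "0, 1")
  sc <- scenario(5, 10, 1, 2, 0.01, T = 500, seed = 3)
  expect_s3_class(sc, "scenario")
  expect_identical(sc$gamma0, 1)
})

test_that("power under the null equals the nominal level", {
  pr <- estimate_power(scenario(8, 10, 1, gamma = 1, alpha = 0.01,
                                T = 1000, seed = 4))
  expect_lt(abs(pr$power - 0.01), 3 * sqrt(0.01 * 0.99 / 1000))
})

test_that("power increases with sample size", {
  p5 <- estimate_power(scenario(5, 10, 1, 2, 0.01, T = 1000, seed = 6))
  p15 <- estimate_power(scenario(15, 10, 1, 2, 0.01, T = 1000, seed = 6))
  se <- sqrt(p5$mc_se^2 + p15$mc_se^2)
  expect_gte(p15$power, p5$power - 3 * se)
  expect_gt(p15$power, p5$power)   # comfortably apart at these settings
})

test_that("power grids are deterministic and complete", {
  g1 <- power_grid(n = c(5, 10), mu = 10, phi = 1, gamma = c(1, 2),
                   alpha = c(0.05, 0.01), T = 300, seed = 9)
  g2 <- power_grid(n = c(5, 10), mu = 10, phi = 1, gamma = c(1, 2),
                   alpha = c(0.05, 0.01), T = 300, seed = 9)
  expect_identical(g1, g2)
  expect_identical(nrow(g1), 2L * 2L * 2L)
  expect_true(all(g1$power >= 0 & g1$power <= 1))
  # critical values per cell do not depend on gamma or alpha ordering
  expect_identical(unique(g1$critical_value[g1$n == 5 & g1$alpha == 0.05]),
                   g1$critical_value[g1$n == 5 & g1$alpha == 0.05][1])
  expect_error(power_grid(n = integer(0), T = 300), "empty")
})

test_that("default grid dimensions mirror the standard study design", {
  # 5 sample sizes x 5 means x 5 dispersions x 5 fold ratios x 4 alphas
  f <- formals(power_grid)
  expect_length(eval(f$n), 5)
  expect_length(eval(f$mu), 5)
  expect_length(eval(f$phi), 5)
  expect_length(eval(f$gamma), 5)
  expect_length(eval(f$alpha), 4)
  expect_identical(eval(f$T), 20000L)
})

test_that("sample-size search returns the smallest qualifying n", {
  res <- sample_size_for_power(10, 1, 2, 0.01, target_power = 0,
                               n_range = 4:8, T = 300, seed = 2)
  expect_identical(res$n, 4L)
  expect_identical(nrow(res$curve), 1L)
  none <- sample_size_for_power(3, 1, 1.05, 0.001, target_power = 0.99,
                                n_range = 3:4, T = 300, seed = 2)
  expect_true(is.na(none$n))
  expect_identical(nrow(none$curve), 2L)
  expect_error(sample_size_for_power(10, 1, 2, 0.01, 0.8,
                                     n_range = integer(0)), "empty")
})

test_that("the design study cell reproduces the recommended sample size", {
  # mu 14, phi 1, 2-fold up-regulation, alpha 0.001, 80% power target.
  # T chosen so that T * alpha is well above the percentile-extrapolation
  # regime the package warns about.
  res <- sample_size_for_power(14, 1, 2, 0.001, target_power = 0.8,
                               n_range = 3:20, T = 5000, seed = 1)
  expect_identical(res$n, 5L)
  expect_true(all(diff(res$curve$power) > 0))
})
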
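test_that("closed-form corrections match hand arithmetic", {
  expect_equal(correct_lambda(0.09, 10), 0.10125)
  expect_equal(correct_lambda(0, 50), 0)
  expect_equal(correct_mu(0.06, 0.6, 20), 0.0991578947368, tolerance = 1e-10)
  expect_equal(correct_mu(0, 0.3, 10), 0)
  expect_equal(correct_netdiv(0.04, 0.6, 20), 0.0661052631579, tolerance = 1e-10)
  expect_equal(correct_netdiv(0, 0.6, 20), 0)
  expect_error(correct_lambda(0.1, 2), "n <= 2")
  expect_error(correct_mu(0.1, -0.1, 10), "nonnegative")
})

test_that("correction factors never shrink estimates and vanish asymptotically", {
  n <- c(3, 5, 10, 100, 1e6)
  expect_true(all(correct_lambda(1, n) > 1))
  expect_equal(correct_lambda(1, 1e8), 1, tolerance = 1e-7)
  expect_true(all(correct_mu(1, 0, n) > 1))
  expect_equal(correct_mu(1, 0, 1e8), 1, tolerance = 1e-7)
  # same factor drives the extinction and net-diversification corrections
  expect_equal(correct_netdiv(0.04, 0.6, 20) / 0.04,
               correct_mu(0.06, 0.6, 20) / 0.06, tolerance = 1e-12)
})

test_that("the full correction set is coherent", {
  est <- list(lambda_hat = 0.09, mu_hat = 0.06, eps_hat = 2/3,
              r_hat = 0.03, n = 20)
  cs <- correct_all(est)
  expect_equal(cs$lambda_corr, 0.095, tolerance = 1e-12)
  expect_equal(cs$mu_corr, 0.103157894737, tolerance = 1e-10)
  expect_equal(cs$tau_corr, 0.198157894737, tolerance = 1e-10)
  expect_equal(cs$tau_corr, cs$lambda_corr + cs$mu_corr)
  # a Yule fit keeps tau_corr = lambda_corr and scales r by n/(n-1)
  ys <- correct_all(list(lambda_hat = 0.2, mu_hat = 0, eps_hat = 0,
                         r_hat = 0.2, n = 25))
  expect_equal(ys$tau_corr, ys$lambda_corr)
  expect_equal(ys$r_corr, 0.2 * 25 / 24)
  expect_error(correct_all(list(lambda_hat = 1, mu_hat = 0, eps_hat = 0,
                                r_hat = 1, n = 2)), "n <= 2")
})

test_that("Yule estimator expectation, bias and variance formulas hold", {
  ye <- yule_expected_estimate(0.3, 4)
  expect_equal(ye$expectation, 0.2)
  expect_equal(ye$bias, -0.1)
  expect_equal(yule_expected_estimate(0.3, 1e7)$expectation, 0.3,
               tolerance = 1e-6)
  # the correction factor is built to invert the expectation exactly
  expect_equal(correct_lambda(ye$expectation, 4), 0.3)
  expect_equal(kendall_variance(0.1, 10), 0.00290988353435, tolerance = 1e-10)
  expect_equal(kendall_variance(0.1, 10, c = 4/3) /
                 kendall_variance(0.1, 10, c = 5/4),
               1.13777777778, tolerance = 1e-9)
  expect_lt(kendall_variance(0.1, 500), 1e-20)
})

test_that("expectation recalibration inverts a noiseless linear map", {
  truth <- seq(0.01, 1, length.out = 50)
  map <- expectation_recalibrate(0.02 + 1.1 * truth, truth)
  expect_equal(map$intercept, 0.02, tolerance = 1e-6)
  expect_equal(map$slope, 1.1, tolerance = 1e-6)
  expect_equal(apply_map(0.02 + 1.1 * truth, map), truth, tolerance = 1e-6)
  ident <- expectation_recalibrate(truth, truth)
  expect_equal(ident$intercept, 0, tolerance = 1e-8)
  expect_equal(ident$slope, 1, tolerance = 1e-8)
  expect_error(expectation_recalibrate(truth[1:5], truth[1:5]), "at least 10")
  expect_error(expectation_recalibrate(rep(1, 20), rep(0.5, 20)), "variance")
})

test_that("Huber fitting resists gross outliers better than least squares", {
  set.seed(31)
  x <- runif(400, 0, 1)
  y <- 0.02 + 1.1 * x + rnorm(400, 0, 0.01)
  bad <- sample(400, 20)
  y[bad] <- y[bad] + rexp(20, rate = 0.2)   # 5% gross outliers
  hub <- huber_line(x, y)$slope
  ls <- unname(coef(lm(y ~ x))[2])
  expect_lt(abs(hub - 1.1), abs(ls - 1.1))
})
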
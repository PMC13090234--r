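test_that("grammars expose the right variables per target", {
  gl <- build_grammar("lambda")
  gm <- build_grammar("mu")
  expect_false("eps" %in% vapply(gl$leaves, `[[`, "", "id"))
  expect_true("eps" %in% vapply(gm$leaves, `[[`, "", "id"))
  expect_equal(gl$theta, "lambda_hat")
  expect_equal(build_grammar("netdiv")$theta, "r_hat")
})

test_that("enumeration is complete, deduplicated and deterministic", {
  g <- build_grammar("lambda")
  cands <- enumerate_expressions(g, max_depth = 2)
  strs <- vapply(cands, `[[`, "", "str")
  depths <- vapply(cands, `[[`, 0L, "depth")
  # the bare estimate sits at depth 1; both ratio corrections at depth 2
  expect_true("lambda_hat" %in% strs[depths == 1])
  expect_true("lambda_hat * (n-1)/(n-2)" %in% strs[depths == 2])
  expect_true("lambda_hat * n/(n-1)" %in% strs[depths == 2])
  # fingerprint dedup: theta * (f1 * 1) must collapse onto theta * f1
  c3 <- enumerate_expressions(g, max_depth = 3)
  s3 <- vapply(c3, `[[`, "", "str")
  expect_false(any(grepl("\\(\\(n-1\\)/\\(n-2\\) \\* 1\\)", s3)))
  expect_equal(anyDuplicated(s3), 0L)
  # deterministic: same canonical list on a second run
  expect_identical(s3, vapply(enumerate_expressions(g, 3), `[[`, "", "str"))
  # the winning extinction correction is expressible
  gm <- build_grammar("mu")
  sm <- vapply(enumerate_expressions(gm, 3), `[[`, "", "str")
  expect_true("mu_hat * (n/(n-1) + eps_hat)" %in% sm)
  expect_error(enumerate_expressions(g, 5), "\\[1, 4\\]")
})

test_that("scoring rewards the true multiplicative correction", {
  set.seed(55)
  n <- sample(3:40, 4000, replace = TRUE)
  lam <- runif(4000, 0.05, 0.5)
  lam_hat <- lam * (n - 2) / (n - 1) * exp(rnorm(4000, 0, 0.05))
  dat <- data.frame(theta_hat = lam_hat, theta_true = lam, n = n)
  g <- build_grammar("lambda")
  cands <- enumerate_expressions(g, 2)
  strs <- vapply(cands, `[[`, "", "str")
  sc <- vapply(cands, function(e) score_expression(e, dat)$raw_score, numeric(1))
  s_f1 <- sc[strs == "lambda_hat * (n-1)/(n-2)"]
  s_f2 <- sc[strs == "lambda_hat * n/(n-1)"]
  s_id <- sc[strs == "lambda_hat"]
  expect_lt(s_f1, s_f2)
  expect_lt(s_f2, s_id)
  # perfect correction scores zero
  perfect <- data.frame(theta_hat = lam, theta_true = lam, n = n)
  expect_equal(score_expression(cands[[which(strs == "lambda_hat")]],
                                perfect)$raw_score, 0)
  # rescaling all rates leaves the candidate ranking unchanged
  dat2 <- transform(dat, theta_hat = 2 * theta_hat, theta_true = 2 * theta_true)
  sc2 <- vapply(cands, function(e) score_expression(e, dat2)$raw_score, numeric(1))
  expect_identical(order(sc), order(sc2))
})

test_that("non-finite expressions are disqualified, not clipped", {
  dat <- data.frame(theta_hat = c(0.1, 0.2), theta_true = c(0.1, 0.2),
                    n = c(2, 5))  # n = 2 row makes (n-1)/(n-2) infinite
  g <- build_grammar("lambda")
  cands <- enumerate_expressions(g, 2)
  strs <- vapply(cands, `[[`, "", "str")
  f1 <- cands[[which(strs == "lambda_hat * (n-1)/(n-2)")]]
  expect_equal(score_expression(f1, dat)$raw_score, Inf)
})

test_that("alpha-grid ranking finds exact crossover intervals", {
  scored <- data.frame(
    expression = c("a", "b"),
    depth = c(3L, 1L),
    raw_score = c(0.01, 0.03))
  # penalized scores cross at alpha = (0.03 - 0.01) / (3 - 1) = 0.01
  rk <- rank_alpha_grid(scored, alpha_range = c(0, 0.02), n_grid = 2001)
  expect_equal(rk$expression, c("a", "b"))
  # at the exact crossover the tie breaks to the shallower expression, so
  # "a" keeps the grid point just below 0.01
  expect_lt(abs(rk$alpha_max[1] - 0.01), 2e-5)
  expect_lt(abs(rk$alpha_min[2] - 0.01), 2e-5)
  expect_equal(rk$omega_min[1], 0)
  expect_equal(rk$omega_max[2], 0.02 * 1)
  # ties break towards smaller depth, then lexicographic string
  tie <- data.frame(expression = c("z", "y", "x"), depth = c(2L, 1L, 1L),
                    raw_score = c(0.02, 0.02, 0.02))
  rk2 <- rank_alpha_grid(tie, alpha_range = c(0, 0.01), n_grid = 11)
  expect_equal(rk2$expression, "x")
})
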
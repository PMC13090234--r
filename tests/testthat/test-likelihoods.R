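test_that("Yule likelihood matches direct substitution on the fixture", {
  tr <- tree3()
  expect_equal(yule_loglik(tr, 0.2), -1.91629073187, tolerance = 1e-9)
  expect_equal(yule_loglik(tr, 0.2, "survival"), yule_loglik(tr, 0.2))
  expect_equal(yule_loglik(tr, 0.2, "n_gt_2"), -1.31967305269, tolerance = 1e-9)
  # conditioning divides by a probability < 1, so it can only raise the loglik
  for (lam in c(0.05, 0.2, 1))
    expect_gte(yule_loglik(tr, lam, "n_gt_2"), yule_loglik(tr, lam))
  expect_error(yule_loglik(tr, -1), "positive")
  expect_error(yule_loglik(cherry_tree(1), 0.2, "n_gt_2"), "cherry")
})

test_that("closed-form Yule MLE equals the numeric argmax", {
  tr <- tree3()
  expect_equal(yule_mle_closed(tr), 0.2)
  expect_equal(yule_mle_closed(cherry_tree(1)), 0)
  grid <- seq(1e-5, 2, by = 1e-5)
  ll <- vapply(grid, function(l) yule_loglik(tr, l), numeric(1))
  expect_equal(grid[which.max(ll)], 0.2, tolerance = 1e-4)
})

test_that("branch-product likelihood matches its closed reductions", {
  tr <- tree3()
  ch <- cherry_tree(10)
  p <- bd_params(0.1, 0.05)
  # cherry under survival conditioning collapses to 2*log(P1/(1-P0));
  # frozen via the eta-parameterization oracle at lambda=.1, mu=.05, t=10
  expect_equal(bd_loglik_branch(ch, p, "survival"), -1.6635931315,
               tolerance = 1e-8)
  # mu = 0 reduction: equals the Nee Yule form minus log((n-1)!)
  for (lam in c(0.1, 0.2, 0.5))
    expect_equal(bd_loglik_branch(tr, bd_params(lam, 0), "survival"),
                 yule_loglik(tr, lam) - log(2), tolerance = 1e-10)
  # conditioning variants differ only through the conditioning divisor
  d <- bd_loglik_branch(tr, p, "n_gt_2") - bd_loglik_branch(tr, p, "survival")
  expect_equal(d, -log(p_gt2_crown(p, 2)) + 2 * log(1 - p_zero(p, 2)),
               tolerance = 1e-10)
  expect_gte(bd_loglik_branch(tr, p, "n_gt_2"),
             bd_loglik_branch(tr, p, "survival"))
})

test_that("oriented and branch-product survival likelihoods agree per tree", {
  trees <- list(tree3(), sim_tree(0.3, 0.1, 6, seed = 2),
                sim_tree(0.2, 0.15, 10, seed = 9))
  for (tr in trees) {
    if (is.null(tr) || tr$n < 3) next
    diffs <- c()
    for (lam in c(0.1, 0.2, 0.3, 0.5, 0.8)) for (fr in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
      p <- bd_params(lam, lam * fr)
      diffs <- c(diffs, bd_loglik_oriented(tr, p) -
                          bd_loglik_branch(tr, p, "survival"))
    }
    # parameter-free constant difference => identical MLEs
    expect_lt(max(diffs) - min(diffs), 1e-9)
  }
})

test_that("the oriented likelihood is undefined on a cherry", {
  expect_error(bd_loglik_oriented(cherry_tree(1), bd_params(0.1, 0.05)),
               class = "bdbias_cherry_undefined")
})

test_that("critical likelihood matches substitution and the mu -> lambda limit", {
  tr <- tree3()
  expect_equal(critical_loglik(tr, 0.5), -4.96981329958, tolerance = 1e-9)
  for (cond in c("none", "survival", "n_gt_2")) {
    lo <- bd_loglik_branch(tr, bd_params(0.5, 0.5 * (1 - 1e-7)), cond)
    hi <- bd_loglik_branch(tr, bd_params(0.5, 0.5 * (1 + 1e-7)), cond)
    cc <- critical_loglik(tr, 0.5, cond)
    expect_equal(lo, cc, tolerance = 1e-4)
    expect_equal(hi, cc, tolerance = 1e-4)
  }
  # ordering of the conditioning divisors
  expect_gte(critical_loglik(tr, 0.5, "n_gt_2"), critical_loglik(tr, 0.5, "survival"))
})

test_that("Yule reduction holds across simulated trees", {
  for (seed in 1:10) {
    tr <- sim_tree(0.4, 0, 4, seed = 900 + seed)
    if (is.null(tr) || tr$n < 3) next
    for (lam in c(0.2, 0.6)) {
      d <- bd_loglik_branch(tr, bd_params(lam, 1e-12), "survival") -
        (yule_loglik(tr, lam) - lgamma(tr$n))
      expect_equal(d, 0, tolerance = 1e-6)
    }
  }
})

test_that("a cherry's survival-conditioned surface has no interior maximum", {
  ch <- cherry_tree(5)
  lams <- exp(seq(log(1e-4), log(2), length.out = 41))
  frs <- seq(0.01, 0.99, length.out = 31)
  ll <- outer(lams, frs, Vectorize(function(l, f)
    bd_loglik_branch(ch, bd_params(l, l * f), "survival")))
  # supremum approached towards (lambda, mu) -> (0, 0): the smallest-lambda
  # slice dominates, and no interior grid point is a local maximum in both
  # directions simultaneously at the global grid max
  expect_equal(which.max(apply(ll, 1, max)), 1L)
  expect_true(max(ll) <= 0 + 1e-12)
  # every achieved level is hit along a curve, not an isolated point:
  # each row (fixed lambda) attains its max at the boundary of the fr range
  row_arg <- apply(ll, 1, which.max)
  expect_true(all(row_arg %in% c(1L, length(frs))))
})
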
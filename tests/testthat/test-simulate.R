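test_that("latin hypercube designs are stratified and reproducible", {
  d <- lhs_design(4, list(x = c(0, 1)), seed = 3)
  strata <- findInterval(d$x, c(0, 0.25, 0.5, 0.75, 1), rightmost.closed = TRUE)
  expect_setequal(strata, 1:4)
  d2 <- lhs_design(4, list(x = c(0, 1)), seed = 3)
  expect_identical(d, d2)
  # birth-death design derives the extinction rate from the sampled fraction
  bd <- lhs_design(50, list(age = c(0, 10), lambda = c(0, 1), epsilon = c(0, 1)),
                   seed = 4)
  expect_equal(bd$mu, bd$lambda * bd$epsilon)
  for (v in c("age", "lambda", "epsilon")) {
    rg <- list(age = c(0, 10), lambda = c(0, 1), epsilon = c(0, 1))[[v]]
    strata <- findInterval(bd[[v]], seq(rg[1], rg[2], length.out = 51),
                           rightmost.closed = TRUE)
    expect_setequal(strata, 1:50)
  }
  expect_error(lhs_design(5, list(x = c(1, 0)), seed = 1), "lo < hi")
})

test_that("a rate-free process always yields a cherry", {
  out <- simulate_crown_tree(bd_params(0, 0), 3, seed = 1)
  expect_equal(out$status, "cherry")
  expect_equal(out$n_extant, 2L)
  expect_equal(out$reconstructed_tree$crown_age, 3)
  expect_equal(out$s, 6)
})

test_that("pruning extinct lineages matches the in-simulator reconstruction", {
  checked <- 0
  for (seed in 1:40) {
    out <- simulate_crown_tree(bd_params(0.35, 0.2), 7, seed = 3000 + seed)
    if (out$status == "extinct") {
      expect_null(out$reconstructed_tree)
      next
    }
    rec <- out$reconstructed_tree
    expect_equal(rec$n, out$n_extant)
    expect_equal(rec$branching_times, as.numeric(out$branching_times),
                 tolerance = 1e-8)
    expect_equal(rec$s, out$s, tolerance = 1e-8)
    checked <- checked + 1
  }
  expect_gt(checked, 5)
})

test_that("pruning a hand-built complete tree sums the collapsed branches", {
  # 4-tip complete tree: D went extinct at age 1; pruning removes D and
  # merges its parent's two half-branches (1 + 1) into C's pendant edge
  txt <- "(((C:2,D:1):1,B:3):1,A:4);"
  phy <- ape::read.tree(text = txt)
  rec <- prune_extinct(phy, extant = c("A", "B", "C"))
  expect_equal(rec$n, 3L)
  expect_equal(rec$s, 4 + 3 + 3 + 1)  # A:4, B:3, C:(2+1 collapsed), root child edge 1
  expect_equal(sort(rec$tip_labels), c("A", "B", "C"))
  # no extinctions: pruning is the identity
  out <- simulate_crown_tree(bd_params(0.4, 0), 4, seed = 5)
  rec2 <- prune_extinct(out$complete_tree)
  expect_equal(rec2$n, out$n_extant)
  expect_equal(rec2$s, out$s, tolerance = 1e-8)
  # crown death on one side: absent
  txt2 <- "((C:1,D:2):2,A:4);"   # C and D both extinct (ages > 0)
  expect_null(prune_extinct(ape::read.tree(text = txt2), extant = "A"))
})

test_that("censoring rules keep the right outcomes without resampling", {
  outs <- list(structure(list(status = "extinct"), class = "sim_outcome"),
               structure(list(status = "cherry"), class = "sim_outcome"),
               structure(list(status = "usable"), class = "sim_outcome"))
  expect_equal(vapply(apply_censoring(outs, "n_gt_2"), `[[`, "", "status"),
               "usable")
  expect_equal(vapply(apply_censoring(outs, "survival"), `[[`, "", "status"),
               c("cherry", "usable"))
})

test_that("simulated tip counts follow the crown Yule distribution", {
  set.seed(424201)
  n <- vapply(1:50000, function(i)
    bdbias:::.sim_crown_cpp(0.5, 0, 1, 2L, FALSE)$n_extant, integer(1))
  for (k in 2:8) {
    p <- p_n_yule(k, 0.5, 1)
    se <- sqrt(p * (1 - p) / 50000)
    expect_lt(abs(mean(n == k) - p), 3 * se + 1e-9)
  }
  # mean tip count of a Yule crown clade is 2*exp(lambda*t)
  set.seed(424202)
  n2 <- vapply(1:10000, function(i)
    bdbias:::.sim_crown_cpp(0.2, 0, 5, 2L, FALSE)$n_extant, integer(1))
  expect_lt(abs(mean(n2) - 2 * exp(1)) / (sd(n2) / sqrt(10000)), 3.5)
})

test_that("single-lineage critical simulation follows Bailey's distribution", {
  set.seed(424203)
  n <- vapply(1:50000, function(i)
    bdbias:::.sim_crown_cpp(0.5, 0.5, 2, 1L, FALSE)$n_extant, integer(1))
  for (k in 0:5) {
    p <- p_n_critical(k, 0.5, 2)   # 1/2^(k+1) at lambda*t = 1
    se <- sqrt(p * (1 - p) / 50000)
    expect_lt(abs(mean(n == k) - p), 3 * se)
  }
})

test_that("crown survival and conditional cherry frequencies match theory", {
  p <- bd_params(0.1, 0.05)
  set.seed(424204)
  st <- vapply(1:20000, function(i)
    bdbias:::.sim_crown_cpp(0.1, 0.05, 10, 2L, FALSE)$status, integer(1))
  psurv <- (1 - p_zero(p, 10))^2
  se <- sqrt(psurv * (1 - psurv) / 20000)
  expect_lt(abs(mean(st > 0) - psurv), 3 * se)
  # among surviving crowns, P(cherry) = P1^2 / (1-P0)^2
  pch <- p_one(p, 10)^2 / (1 - p_zero(p, 10))^2
  sech <- sqrt(pch * (1 - pch) / sum(st > 0))
  expect_lt(abs(mean(st[st > 0] == 1) - pch), 3 * sech)
})

test_that("simulated reconstructed trees pass treeio validation", {
  for (seed in 1:15) {
    out <- simulate_crown_tree(bd_params(0.5, 0.25), 5, seed = 5000 + seed)
    if (out$status == "extinct") next
    expect_s3_class(as_recon_tree(out$reconstructed_tree$phylo), "recon_tree")
  }
})

test_that("batch simulation is reproducible from the master seed", {
  a <- bdbias:::.sim_batch(c(0.3, 0.5), c(0.1, 0.2), c(5, 5), seed = 9)
  b <- bdbias:::.sim_batch(c(0.3, 0.5), c(0.1, 0.2), c(5, 5), seed = 9)
  expect_identical(a, b)
})
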
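# Grammar-based exhaustive symbolic regression for multiplicative
# bias-correction expressions. Every candidate has the dimensionally
# consistent form theta_hat * c(.), where c is a dimensionless expression
# over sample size n, the primitive ratio tokens (n-1)/(n-2) and n/(n-1),
# the estimated extinction fraction (for extinction / net-diversification
# targets), and a small constant pool. Candidates are scored by a Huber
# loss on deviations from the 1:1 line against the generating values and
# ranked under a depth penalty Omega = alpha * depth across an alpha grid.

.symreg_leaves <- function(with_eps) {
  leaves <- list(
    list(type = "leaf", id = "n",    str = "n",           depth = 1L),
    list(type = "leaf", id = "f1",   str = "(n-1)/(n-2)", depth = 1L),
    list(type = "leaf", id = "f2",   str = "n/(n-1)",     depth = 1L),
    list(type = "leaf", id = "c0.5", str = "0.5",         depth = 1L, value = 0.5),
    list(type = "leaf", id = "c1",   str = "1",           depth = 1L, value = 1),
    list(type = "leaf", id = "c2",   str = "2",           depth = 1L, value = 2))
  if (with_eps)
    leaves <- append(leaves,
                     list(list(type = "leaf", id = "eps", str = "eps_hat", depth = 1L)),
                     after = 3L)
  leaves
}

.eval_node <- function(node, data) {
  if (node$type == "leaf") {
    switch(node$id,
      n = data$n,
      f1 = (data$n - 1) / (data$n - 2),
      f2 = data$n / (data$n - 1),
      eps = data$eps_hat,
      node$value)
  } else {
    l <- .eval_node(node$l, data)
    r <- .eval_node(node$r, data)
    switch(node$op, "+" = l + r, "-" = l - r, "*" = l * r, "/" = l / r)
  }
}

#' Build a correction-expression grammar
#'
#' Variables available to the dimensionless factor: \code{n}, the ratio
#' tokens \code{(n-1)/(n-2)} and \code{n/(n-1)}, constants
#' \{0.5, 1, 2\}, and -- for the extinction and net-diversification
#' targets -- the estimated extinction fraction \code{eps_hat} (required
#' to express the winning extinction correction). Operators: +, -, *, /.
#' Productions are constrained so every complete expression is
#' \code{theta_hat * (dimensionless)}; the constant pool is minimal for the
#' corrections the search is expected to recover.
#'
#' @param target \code{"lambda"}, \code{"mu"} or \code{"netdiv"}; selects
#'   the estimate \code{theta_hat} the expressions correct.
#' @return An object of class \code{"bd_grammar"}.
#' @export
build_grammar <- function(target = c("lambda", "mu", "netdiv")) {
  target <- match.arg(target)
  structure(list(
    target = target,
    theta = switch(target, lambda = "lambda_hat", mu = "mu_hat", netdiv = "r_hat"),
    leaves = .symreg_leaves(with_eps = target != "lambda"),
    ops = c("+", "-", "*", "/")
  ), class = "bd_grammar")
}

# deterministic probe points for duplicate detection (evaluation
# fingerprints agreeing within 1e-10 identify algebraically equal factors)
.symreg_probes <- function() {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(987654L)
  list(n = runif(64, 2.05, 500), eps_hat = runif(64, 0, 2))
}

#' Enumerate all admissible correction expressions
#'
#' Complete enumeration of expressions \code{theta_hat * c} with the
#' expression-tree depth at most \code{max_depth}. Depth counts every
#' variable, ratio token and constant as a leaf of depth 1 and each
#' operator as one extra level; the bare estimate \code{theta_hat} (the
#' factor c = 1) has depth 1. Duplicates are removed by evaluation
#' fingerprint on 64 fixed probe points (agreement within 1e-10), keeping
#' the shallowest representative, so e.g. \code{theta_hat * (f * 1)}
#' collapses onto \code{theta_hat * f}. Enumeration is deterministic.
#'
#' @param grammar a \code{"bd_grammar"} from \code{\link{build_grammar}}.
#' @param max_depth maximum expression depth, between 1 and 4 (the space
#'   grows combinatorially beyond that, and deeper searches are refused).
#' @return A list of candidates, each a list with \code{str} (canonical
#'   string), \code{depth} and \code{c} (the factor's expression tree;
#'   \code{NULL} for the bare estimate).
#' @export
enumerate_expressions <- function(grammar, max_depth = 4) {
  stopifnot(inherits(grammar, "bd_grammar"))
  if (max_depth < 1 || max_depth > 4)
    stop("max_depth must be in [1, 4]; deeper expression spaces grow combinatorially")
  probes <- .symreg_probes()
  seen <- new.env(parent = emptyenv(), hash = TRUE)
  pool <- vector("list", 0L)
  add <- function(node) {
    v <- rep_len(.eval_node(node, probes), 64L)
    if (any(!is.finite(v))) return(invisible())
    key <- paste(signif(v, 10), collapse = "|")
    if (!is.null(seen[[key]])) return(invisible())
    seen[[key]] <- TRUE
    pool[[length(pool) + 1L]] <<- node
    invisible()
  }
  for (lf in grammar$leaves) add(lf)
  c_max <- max_depth - 1L
  d <- 2L
  while (d <= c_max) {
    prev <- pool
    for (i in seq_along(prev)) for (j in seq_along(prev)) {
      if (max(prev[[i]]$depth, prev[[j]]$depth) != d - 1L) next
      for (op in grammar$ops) {
        add(list(type = "op", op = op, l = prev[[i]], r = prev[[j]],
                 str = paste0("(", prev[[i]]$str, " ", op, " ", prev[[j]]$str, ")"),
                 depth = d))
      }
    }
    d <- d + 1L
  }
  out <- lapply(pool, function(nd) {
    if (nd$type == "leaf" && identical(nd$id, "c1"))
      list(str = grammar$theta, depth = 1L, c = NULL)
    else
      list(str = paste(grammar$theta, "*", nd$str), depth = nd$depth + 1L, c = nd)
  })
  Filter(function(cand) cand$depth <= max_depth, out)
}

# Lean IRLS Huber line fit (tuning k, MAD scale, at most `maxit`
# reweighted least-squares steps). Same estimator as MASS::rlm with
# psi.huber/k/MAD scale, implemented without model-frame overhead so the
# expression search can fit tens of thousands of candidate regressions.
.huber_irls <- function(x, y, k = 1.345, tol = 1e-8, maxit = 50) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx <= 0) return(c(intercept = my, slope = 0))
  b <- sum((x - mx) * (y - my)) / sxx
  a <- my - b * mx
  for (it in seq_len(maxit)) {
    r <- y - a - b * x
    sc <- median(abs(r)) / 0.6744898
    if (!is.finite(sc) || sc < 1e-12) break
    w <- pmin(1, k * sc / abs(r))
    w[!is.finite(w)] <- 1
    sw <- sum(w)
    mxw <- sum(w * x) / sw; myw <- sum(w * y) / sw
    sxxw <- sum(w * (x - mxw)^2)
    if (sxxw <= 0) break
    b_new <- sum(w * (x - mxw) * (y - myw)) / sxxw
    a_new <- myw - b_new * mxw
    if (abs(b_new - b) + abs(a_new - a) < tol * (1 + abs(a) + abs(b))) {
      a <- a_new; b <- b_new
      break
    }
    a <- a_new; b <- b_new
  }
  c(intercept = a, slope = b)
}

#' Score a correction expression against generating values
#'
#' Evaluates the candidate on each row of \code{data}, fits a robust
#' (Huber, tuning constant 1.345, MAD scale) regression of the expression
#' output on the generating values \code{theta_true}, and scores the
#' squared deviation of the fitted relationship from the 1:1 line:
#' \deqn{raw = mean((a + b\,\theta_{true} - \theta_{true})^2)}
#' over the observed generating values. An expression that corrects the
#' estimator perfectly tracks the identity line and scores (near) zero;
#' expressions that merely shrink the spread of the estimates are
#' penalized through their departing slope. Expressions producing a
#' non-finite value on any row are disqualified with an infinite score.
#'
#' @param expr a candidate from \code{\link{enumerate_expressions}}.
#' @param data a \code{data.frame} with columns \code{theta_hat},
#'   \code{theta_true}, \code{n} and (for extinction-type grammars)
#'   \code{eps_hat}.
#' @param k Huber tuning constant.
#' @param fit_line return the regression slope and intercept as well?
#' @return A list with \code{raw_score} and, when requested, \code{slope}
#'   and \code{intercept}.
#' @export
score_expression <- function(expr, data, k = 1.345, fit_line = FALSE) {
  fac <- if (is.null(expr$c)) 1 else .eval_node(expr$c, data)
  pred <- data$theta_hat * fac
  if (any(!is.finite(pred)))
    return(list(raw_score = Inf, slope = NA_real_, intercept = NA_real_))
  cf <- .huber_irls(data$theta_true, pred, k = k)
  out <- list(raw_score = mean((cf[1] + (cf[2] - 1) * data$theta_true)^2))
  if (fit_line) {
    out$slope <- unname(cf[2]); out$intercept <- unname(cf[1])
  }
  out
}

#' Rank scored expressions across a grid of complexity penalties
#'
#' For each penalty weight \eqn{\alpha} on a dense grid, the winning
#' expression minimizes the penalized score
#' \eqn{raw + \Omega}, \eqn{\Omega = \alpha \cdot depth}. Whenever the
#' top-ranked expression changes along the grid, the interval of
#' \eqn{\alpha} over which the previous expression was optimal is
#' recorded, with \eqn{\Omega} at its endpoints. Ties are broken towards
#' smaller depth, then lexicographically on the canonical string.
#'
#' @param scored a \code{data.frame} with columns \code{expression},
#'   \code{depth}, \code{raw_score} (one row per candidate).
#' @param alpha_range \code{c(0, alpha_max)}.
#' @param n_grid number of grid points, >= 2.
#' @return A \code{data.frame} with one row per optimality interval:
#'   \code{expression}, \code{depth}, \code{raw_score}, \code{alpha_min},
#'   \code{alpha_max}, \code{omega_min}, \code{omega_max}.
#' @export
rank_alpha_grid <- function(scored, alpha_range = c(0, 0.02), n_grid = 5000) {
  stopifnot(n_grid >= 2, length(alpha_range) == 2, alpha_range[1] < alpha_range[2])
  ok <- is.finite(scored$raw_score)
  scored <- scored[ok, , drop = FALSE]
  if (!nrow(scored)) stop("no finite-score candidates to rank")
  # only the best raw score at each depth can ever win under Omega = alpha*depth
  bests <- do.call(rbind, lapply(split(scored, scored$depth), function(df) {
    df[order(df$raw_score, df$expression), , drop = FALSE][1L, ]
  }))
  bests <- bests[order(bests$depth), , drop = FALSE]
  alphas <- seq(alpha_range[1], alpha_range[2], length.out = n_grid)
  win <- vapply(alphas, function(a) {
    pen <- bests$raw_score + a * bests$depth
    order(pen, bests$depth, bests$expression)[1L]
  }, integer(1))
  runs <- rle(win)
  stops <- cumsum(runs$lengths)
  startsv <- c(1L, head(stops, -1L) + 1L)
  data.frame(
    expression = bests$expression[runs$values],
    depth = bests$depth[runs$values],
    raw_score = bests$raw_score[runs$values],
    alpha_min = alphas[startsv],
    alpha_max = alphas[stops],
    omega_min = alphas[startsv] * bests$depth[runs$values],
    omega_max = alphas[stops] * bests$depth[runs$values],
    stringsAsFactors = FALSE)
}

#' Exhaustive symbolic-regression search for a bias correction
#'
#' Convenience pipeline: build the grammar for \code{target}, enumerate
#' all admissible expressions to \code{max_depth}, score them against the
#' generating values, and rank them across the \eqn{\alpha} grid.
#'
#' @param data a \code{data.frame} with columns \code{theta_hat},
#'   \code{theta_true}, \code{n} and, for \code{target != "lambda"},
#'   \code{eps_hat}.
#' @param target \code{"lambda"}, \code{"mu"} or \code{"netdiv"}.
#' @param alpha_max upper end of the penalty grid.
#' @param max_depth maximum expression depth (<= 4).
#' @param n_grid number of alpha grid points.
#' @param top_k how many top candidates (by raw score) to report with
#'   robust-regression slopes.
#' @return A list with \code{scored} (all candidates), \code{table} (top
#'   \code{top_k} with slopes/intercepts) and \code{ranking} (the
#'   alpha-interval table).
#' @export
symreg_search <- function(data, target = c("lambda", "mu", "netdiv"),
                          alpha_max = 0.02, max_depth = 4, n_grid = 5000,
                          top_k = 10) {
  target <- match.arg(target)
  grammar <- build_grammar(target)
  cands <- enumerate_expressions(grammar, max_depth = max_depth)
  raw <- vapply(cands, function(e) score_expression(e, data)$raw_score, numeric(1))
  scored <- data.frame(
    expression = vapply(cands, `[[`, character(1), "str"),
    depth = vapply(cands, `[[`, integer(1), "depth"),
    raw_score = raw,
    stringsAsFactors = FALSE)
  ord <- order(scored$raw_score, scored$depth, scored$expression)
  top <- head(ord, top_k)
  tab <- scored[top, , drop = FALSE]
  lines <- lapply(cands[top], score_expression, data = data, fit_line = TRUE)
  tab$slope <- vapply(lines, `[[`, numeric(1), "slope")
  tab$intercept <- vapply(lines, `[[`, numeric(1), "intercept")
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  list(scored = scored, table = tab,
       ranking = rank_alpha_grid(scored, alpha_range = c(0, alpha_max),
                                 n_grid = n_grid))
}
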
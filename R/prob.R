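#' Probability kernels of the constant-rate birth-death process
#'
#' Closed-form single-lineage and crown-clade probabilities used to
#' condition the tree likelihoods. For a single lineage evolving for time
#' \code{t} under rates (lambda, mu) with r = lambda - mu:
#' \itemize{
#'   \item \code{p_zero}: probability of extinction,
#'     \eqn{P_0(t) = 1 - r / (\lambda - \mu e^{-rt})};
#'   \item \code{p_one}: probability of exactly one extant descendant,
#'     \eqn{P_1(t) = r^2 e^{-rt} / (\lambda - \mu e^{-rt})^2};
#'   \item \code{p_gt2_crown}: probability that a crown clade of age
#'     \code{t} both survives (each root daughter leaves descendants) and
#'     has more than two extant tips,
#'     \eqn{P_{n>2}(t) = [1 - P_0(t)]^2 - P_1(t)^2}.
#' }
#' When \code{|lambda - mu| < 1e-9 * max(lambda, mu)} the critical
#' (\code{lambda = mu}) forms are used to avoid catastrophic cancellation.
#' All terms are evaluated with \code{expm1} for stability near r = 0.
#'
#' Note on \code{p_one}: some published statements of this kernel carry a
#' denominator \eqn{(\lambda + (\lambda-\mu)e^{-rt})^2}, which fails the
#' sanity check \eqn{P_1(0) = 1}. This package implements the standard form
#' above, under which \eqn{P_1(0) = 1} and the single-lineage tip-count
#' distribution sums to one.
#'
#' @param params a \code{\link{bd_params}} object.
#' @param t time (age), >= 0; vectorized.
#' @return Probabilities in [0, 1].
#' @name bd-kernels
NULL

.bd_denominator <- function(lambda, mu, r, t) {
  # lambda - mu * exp(-r t), written stably
  r - mu * expm1(-r * t)
}

#' @rdname bd-kernels
#' @export
p_zero <- function(params, t) {
  params <- .as_bd_params(params)
  lambda <- params$lambda; mu <- params$mu
  stopifnot(all(t >= 0))
  if (lambda == 0 && mu == 0) return(rep(0, length(t)))
  if (abs(lambda - mu) < 1e-9 * max(lambda, mu))
    return(lambda * t / (1 + lambda * t))
  r <- lambda - mu
  1 - r / .bd_denominator(lambda, mu, r, t)
}

#' @rdname bd-kernels
#' @export
p_one <- function(params, t) {
  params <- .as_bd_params(params)
  lambda <- params$lambda; mu <- params$mu
  stopifnot(all(t >= 0))
  if (lambda == 0 && mu == 0) return(rep(1, length(t)))
  if (abs(lambda - mu) < 1e-9 * max(lambda, mu))
    return(1 / (1 + lambda * t)^2)
  r <- lambda - mu
  D <- .bd_denominator(lambda, mu, r, t)
  r^2 * exp(-r * t) / D^2
}

#' @rdname bd-kernels
#' @export
p_gt2_crown <- function(params, t) {
  (1 - p_zero(params, t))^2 - p_one(params, t)^2
}

#' Tip-count probability of a crown Yule clade
#'
#' Probability that a crown clade (two initial lineages) evolving without
#' extinction for time \code{t} at speciation rate \code{lambda} has
#' exactly \code{n} extant tips:
#' \eqn{P_n = (n-1) e^{-2\lambda t} (1 - e^{-\lambda t})^{n-2}}, n >= 2.
#'
#' @param n integer tip count, >= 2; vectorized.
#' @param lambda speciation rate, > 0.
#' @param t clade age, > 0.
#' @return Probability.
#' @export
p_n_yule <- function(n, lambda, t) {
  if (any(n < 2)) stop("a surviving crown Yule clade has at least 2 tips")
  stopifnot(lambda > 0, t > 0)
  (n - 1) * exp(-2 * lambda * t) * (-expm1(-lambda * t))^(n - 2)
}

#' Single-lineage tip-count probability under the critical branching process
#'
#' For \code{lambda = mu}, the probability that one lineage has exactly
#' \code{n} descendants after time \code{t}:
#' \eqn{P_n(t) = (\lambda t)^{n-1} / (1 + \lambda t)^{n+1}} for n >= 1,
#' with \eqn{P_0(t) = \lambda t / (1 + \lambda t)}.
#'
#' @param n integer tip count, >= 0; vectorized.
#' @param lambda rate (= both speciation and extinction), > 0.
#' @param t time, > 0.
#' @return Probability.
#' @export
p_n_critical <- function(n, lambda, t) {
  if (any(n < 0)) stop("n must be nonnegative")
  stopifnot(lambda > 0, t > 0)
  x <- lambda * t
  out <- x^(n - 1) / (1 + x)^(n + 1)
  out[n == 0] <- x / (1 + x)
  out
}

#' Crown survival-and-size probability under the critical branching process
#'
#' Probability that a crown clade of age \code{t} under \code{lambda = mu}
#' both survives and has more than two extant tips:
#' \eqn{P_{n>2}(t) = [1 - P_0(t)]^2 - P_1(t)^2} with the critical kernels.
#'
#' @inheritParams p_n_critical
#' @return Probability.
#' @export
p_gt2_crown_critical <- function(lambda, t) {
  stopifnot(lambda > 0, all(t > 0))
  surv <- 1 / (1 + lambda * t)      # 1 - P0
  p1 <- surv^2
  surv^2 - p1^2
}
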
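#' Small-sample bias correction for the speciation rate
#'
#' Under the Yule process conditioned on the observed tip count, the MLE
#' \eqn{\hat\lambda = (n-2)/s} has expectation
#' \eqn{\lambda (n-2)/(n-1)}; multiplying by \eqn{(n-1)/(n-2)} removes the
#' bias. The same multiplicative correction is the recommended one for the
#' speciation rate under the general birth-death model.
#'
#' @param lambda_hat estimated speciation rate(s).
#' @param n tip count(s), >= 3.
#' @return Corrected rate(s).
#' @examples
#' correct_lambda(0.09, 10)  # 0.10125
#' @export
correct_lambda <- function(lambda_hat, n) {
  if (any(n <= 2)) stop("the correction factor (n-1)/(n-2) is undefined for n <= 2")
  if (any(lambda_hat < 0)) stop("lambda_hat must be nonnegative")
  lambda_hat * (n - 1) / (n - 2)
}

#' Bias correction for the extinction rate
#'
#' The recommended multiplicative correction for the extinction rate under
#' the birth-death model depends on both sample size and the estimated
#' extinction fraction:
#' \eqn{\hat\mu_{corr} = \hat\mu (n/(n-1) + \hat\varepsilon)}.
#'
#' @param mu_hat estimated extinction rate(s).
#' @param eps_hat estimated extinction fraction(s) \eqn{\hat\mu/\hat\lambda}.
#' @param n tip count(s), >= 2.
#' @return Corrected rate(s).
#' @export
correct_mu <- function(mu_hat, eps_hat, n) {
  if (any(n < 2)) stop("n must be at least 2")
  if (any(mu_hat < 0) || any(eps_hat < 0)) stop("inputs must be nonnegative")
  mu_hat * (n / (n - 1) + eps_hat)
}

#' Bias correction for net diversification
#'
#' Applies the same factor as \code{\link{correct_mu}} to the raw net
#' diversification estimate \eqn{\hat r = \hat\lambda - \hat\mu} computed
#' from the uncorrected MLEs (not to the difference of corrected rates):
#' \eqn{\hat r_{corr} = \hat r (n/(n-1) + \hat\varepsilon)}.
#'
#' @param r_hat raw net-diversification estimate(s).
#' @param eps_hat estimated extinction fraction(s).
#' @param n tip count(s), >= 2.
#' @return Corrected rate(s).
#' @export
correct_netdiv <- function(r_hat, eps_hat, n) {
  if (any(n < 2)) stop("n must be at least 2")
  if (any(eps_hat < 0)) stop("eps_hat must be nonnegative")
  r_hat * (n / (n - 1) + eps_hat)
}

#' Apply all recommended corrections to a birth-death fit
#'
#' @param est a \code{"bd_fit"} (or list with \code{lambda_hat},
#'   \code{mu_hat}, \code{eps_hat}, \code{r_hat}, \code{n}); \code{n} must
#'   exceed 2.
#' @return A list of class \code{"correction_set"} with
#'   \code{lambda_corr}, \code{mu_corr}, \code{tau_corr}
#'   (= \code{lambda_corr + mu_corr}), \code{r_corr} and the inputs.
#' @export
correct_all <- function(est) {
  if (any(est$n <= 2)) stop("corrections are undefined for n <= 2")
  lambda_corr <- correct_lambda(est$lambda_hat, est$n)
  mu_corr <- correct_mu(est$mu_hat, est$eps_hat, est$n)
  structure(list(
    lambda_corr = lambda_corr,
    mu_corr = mu_corr,
    tau_corr = lambda_corr + mu_corr,
    r_corr = correct_netdiv(est$r_hat, est$eps_hat, est$n),
    inputs = est[c("lambda_hat", "mu_hat", "eps_hat", "r_hat", "n")]
  ), class = "correction_set")
}

#' Expectation and bias of the Yule speciation-rate MLE
#'
#' Conditional on tip count \code{n}, the Yule MLE has
#' \eqn{E(\hat\lambda \mid n) = \lambda (n-2)/(n-1)} and bias
#' \eqn{-\lambda/(n-1)}.
#'
#' @param lambda generating speciation rate.
#' @param n tip count, >= 3.
#' @return A list with \code{expectation} and \code{bias}.
#' @export
yule_expected_estimate <- function(lambda, n) {
  if (any(n <= 2)) stop("n must exceed 2")
  expectation <- lambda * (n - 2) / (n - 1)
  list(expectation = expectation, bias = expectation - lambda)
}

#' Fixed-time variance of the Yule estimator
#'
#' Kendall's variance for a Yule process of fixed age \code{t} (tip number
#' varying across replicates):
#' \eqn{Var(\hat\lambda) = \lambda^2 / (2(e^{\lambda t} - 1))}, scaled by
#' \eqn{c^2} for a corrected estimator \eqn{c\hat\lambda}. Illustrates the
#' bias-variance trade-off between correction factors such as
#' \eqn{(n-1)/(n-2)} and \eqn{n/(n-1)}.
#'
#' @param lambda speciation rate, > 0.
#' @param t clade age, > 0.
#' @param c multiplicative correction factor (default 1).
#' @return The variance.
#' @export
kendall_variance <- function(lambda, t, c = 1) {
  stopifnot(lambda > 0, t > 0)
  c^2 * lambda^2 / (2 * expm1(lambda * t))
}

#' Robust (Huber) line fit
#'
#' Huber M-estimation of \code{y = a + b x} via \code{MASS::rlm} with
#' tuning constant 1.345 and MAD scale (the standard 95-percent-efficiency
#' choice), at most 50 IRLS iterations.
#'
#' @param x predictor (here: generating values).
#' @param y response (here: estimates).
#' @param k Huber tuning constant.
#' @param maxit maximum IRLS iterations.
#' @return A list with \code{intercept} and \code{slope}.
#' @export
huber_line <- function(x, y, k = 1.345, maxit = 50) {
  keep <- is.finite(x) & is.finite(y)
  if (sum(keep) < 3) stop("need at least 3 finite (x, y) pairs")
  fit <- suppressWarnings(
    MASS::rlm(y[keep] ~ x[keep], psi = MASS::psi.huber, k = k,
              scale.est = "MAD", maxit = maxit))
  cf <- unname(coef(fit))
  list(intercept = cf[1], slope = cf[2])
}

#' Expectation-based linear recalibration
#'
#' Fits a robust (Huber) regression of corrected estimates on their
#' generating values, \eqn{\theta_{corr} = a + b\,\theta_{true}}, and
#' returns the linear map; \code{\link{apply_map}} inverts it as
#' \eqn{\theta' = (\theta_{corr} - a)/b}, recentering corrected estimates
#' on their expected values under the simulation design.
#'
#' @param corrected corrected estimates.
#' @param truth generating values (same length, >= 10 pairs, nonzero
#'   variance).
#' @param tag optional parameter tag (e.g. \code{"lambda"}).
#' @return A list of class \code{"linear_map"} with \code{intercept},
#'   \code{slope} and \code{tag}.
#' @export
expectation_recalibrate <- function(corrected, truth, tag = NULL) {
  if (length(corrected) != length(truth)) stop("lengths differ")
  if (length(truth) < 10) stop("need at least 10 (corrected, truth) pairs")
  if (stats::var(truth) <= 0) stop("degenerate design: truth has no variance")
  ln <- huber_line(truth, corrected)
  if (!is.finite(ln$slope) || abs(ln$slope) < 1e-12)
    stop("degenerate recalibration: slope is zero")
  structure(list(intercept = ln$intercept, slope = ln$slope, tag = tag),
            class = "linear_map")
}

#' @rdname expectation_recalibrate
#' @param value value(s) to recalibrate.
#' @param map a \code{"linear_map"}.
#' @export
apply_map <- function(value, map) {
  (value - map$intercept) / map$slope
}
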
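#' Yule log-likelihood of a reconstructed tree
#'
#' Nee's labeled-tree Yule likelihood
#' \eqn{L(\lambda) = (n-1)!\,\lambda^{n-2} e^{-\lambda s}}, where \code{s}
#' is the total edge length. Crown survival is automatic under the Yule
#' process, so \code{condition = "none"} and \code{"survival"} coincide;
#' \code{condition = "n_gt_2"} divides by the probability
#' \eqn{1 - e^{-2\lambda t}} that a clade of the same age and rate has more
#' than two tips.
#'
#' @param tree a \code{"recon_tree"} object.
#' @param lambda speciation rate, > 0 (vectorized).
#' @param condition one of \code{"none"}, \code{"survival"},
#'   \code{"n_gt_2"}.
#' @return Log-likelihood (natural log).
#' @export
yule_loglik <- function(tree, lambda, condition = c("none", "survival", "n_gt_2")) {
  condition <- match.arg(condition)
  tree <- as_recon_tree(tree)
  if (any(lambda <= 0)) stop("lambda must be positive")
  n <- tree$n
  ll <- lgamma(n) + (n - 2) * log(lambda) - lambda * tree$s
  if (condition == "n_gt_2") {
    if (n <= 2)
      stop("conditioning on n > 2 is undefined for a cherry tree (censored by assumption)")
    ll <- ll - log(-expm1(-2 * lambda * tree$crown_age))
  }
  ll
}

#' Closed-form Yule maximum-likelihood estimate
#'
#' \eqn{\hat\lambda = (n - 2)/s}. Zero for a cherry tree (no speciation
#' event beyond the crown was observed).
#'
#' @param tree a \code{"recon_tree"} object.
#' @return The rate estimate.
#' @export
yule_mle_closed <- function(tree) {
  tree <- as_recon_tree(tree)
  if (tree$s <= 0) stop("total edge length must be positive")
  (tree$n - 2) / tree$s
}

.stop_cherry <- function(msg) {
  stop(structure(class = c("bdbias_cherry_undefined", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

.stop_nonidentifiable <- function(msg) {
  stop(structure(class = c("bdbias_nonidentifiable", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Branch-product birth-death log-likelihood
#'
#' The unconditioned likelihood is a product over the \code{2m} branch
#' segments of the reconstructed tree,
#' \deqn{L(\lambda,\mu) = \Big[\prod_{i=1}^{2m} e^{-r(t_{i,r}-t_{i,t})}
#'   \frac{(\lambda-\mu e^{-r t_{i,t}})^2}{(\lambda-\mu e^{-r t_{i,r}})^2}
#'   \Big]\lambda^m,}
#' with \eqn{r = \lambda-\mu} and \eqn{t_{i,r} > t_{i,t}} the rootward and
#' tipward ages of segment i. Because the product runs over branches rather
#' than over speciation events it is defined down to \code{n = 2}.
#' Conditioning on crown survival divides by \eqn{[1-P_0(t)]^2} and lowers
#' the \eqn{\lambda} exponent to \eqn{m-1} (the crown speciation event is
#' conditioned on, not observed); conditioning on \code{n > 2} divides by
#' \eqn{[1-P_0(t)]^2 - P_1(t)^2} instead. \code{t} is the crown age of the
#' observed tree. Rates with \code{lambda} essentially equal to \code{mu}
#' dispatch to the critical branching form.
#'
#' @param tree a \code{"recon_tree"} object.
#' @param params a \code{\link{bd_params}} object.
#' @param condition one of \code{"none"}, \code{"survival"},
#'   \code{"n_gt_2"}.
#' @return Log-likelihood (natural log).
#' @export
bd_loglik_branch <- function(tree, params, condition = c("none", "survival", "n_gt_2")) {
  condition <- match.arg(condition)
  tree <- as_recon_tree(tree)
  params <- .as_bd_params(params)
  lambda <- params$lambda; mu <- params$mu
  if (lambda <= 0) stop("lambda must be positive")
  if (mu < 0) stop("mu must be nonnegative")
  n <- tree$n; m <- tree$m; t1 <- tree$crown_age
  if (condition == "n_gt_2" && n <= 2)
    stop("conditioning on n > 2 is undefined for a cherry tree (censored by assumption)")
  tr <- tree$branch_rootward; tt <- tree$branch_tipward
  if (abs(lambda - mu) < 1e-9 * max(lambda, mu)) {
    ll <- sum(2 * log1p(lambda * tt) - 2 * log1p(lambda * tr))
    lcond <- switch(condition,
      none = m * log(lambda),
      survival = (m - 1) * log(lambda) + 2 * log1p(lambda * t1),
      n_gt_2 = (m - 1) * log(lambda) - log(p_gt2_crown_critical(lambda, t1)))
    return(ll + lcond)
  }
  r <- lambda - mu
  ll <- sum(-r * (tr - tt) +
              2 * log(abs(.bd_denominator(lambda, mu, r, tt))) -
              2 * log(abs(.bd_denominator(lambda, mu, r, tr))))
  lcond <- switch(condition,
    none = m * log(lambda),
    survival = (m - 1) * log(lambda) - 2 * log(1 - p_zero(params, t1)),
    n_gt_2 = (m - 1) * log(lambda) - log(p_gt2_crown(params, t1)))
  ll + lcond
}

#' Oriented birth-death log-likelihood conditioned on crown survival
#'
#' The speciation-times formulation
#' \deqn{f(T \mid t_1 = t_{crown}) = \Big(\frac{p_1(t_1)}{1-p_0(t_1)}\Big)^2
#'   \prod_{i=2}^{n-1} \lambda\, p_1(t_i),}
#' where the product runs over the non-crown branching times. For a cherry
#' tree (\code{n = 2}) the vector of speciation times is empty and the
#' likelihood cannot be evaluated under this formulation; an error of class
#' \code{"bdbias_cherry_undefined"} is raised rather than a silent zero.
#'
#' @param tree a \code{"recon_tree"} object with \code{n >= 3}.
#' @param params a \code{\link{bd_params}} object with
#'   \code{lambda != mu}.
#' @return Log-likelihood (natural log).
#' @export
bd_loglik_oriented <- function(tree, params) {
  tree <- as_recon_tree(tree)
  params <- .as_bd_params(params)
  if (tree$n <= 2)
    .stop_cherry(paste0(
      "the oriented likelihood is undefined for a cherry tree (n = 2): ",
      "the vector of non-crown speciation times is empty"))
  if (params$lambda <= 0) stop("lambda must be positive")
  t1 <- tree$crown_age
  inner <- tree$branching_times[-1L]
  2 * (log(p_one(params, t1)) - log(1 - p_zero(params, t1))) +
    sum(log(params$lambda) + log(p_one(params, inner)))
}

#' Critical branching process log-likelihood
#'
#' For \code{lambda = mu} the branch-product likelihood simplifies to
#' \deqn{L(\lambda) = \Big[\prod_{i=1}^{2m}
#'   \frac{(1+\lambda t_{i,t})^2}{(1+\lambda t_{i,r})^2}\Big] \lambda^m,}
#' with the same conditioning variants as
#' \code{\link{bd_loglik_branch}} built from the critical kernels.
#'
#' @param tree a \code{"recon_tree"} object.
#' @param lambda rate (= both speciation and extinction), > 0.
#' @param condition one of \code{"none"}, \code{"survival"},
#'   \code{"n_gt_2"}.
#' @return Log-likelihood (natural log).
#' @export
critical_loglik <- function(tree, lambda, condition = c("none", "survival", "n_gt_2")) {
  condition <- match.arg(condition)
  tree <- as_recon_tree(tree)
  if (lambda <= 0) stop("lambda must be positive")
  if (condition == "n_gt_2" && tree$n <= 2)
    stop("conditioning on n > 2 is undefined for a cherry tree (censored by assumption)")
  m <- tree$m; t1 <- tree$crown_age
  ll <- sum(2 * log1p(lambda * tree$branch_tipward) -
              2 * log1p(lambda * tree$branch_rootward))
  lcond <- switch(condition,
    none = m * log(lambda),
    survival = (m - 1) * log(lambda) + 2 * log1p(lambda * t1),
    n_gt_2 = (m - 1) * log(lambda) - log(p_gt2_crown_critical(lambda, t1)))
  ll + lcond
}
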
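# Maximum-likelihood estimation of (lambda, mu) in the (turnover,
# extinction fraction) parameterization, with Hessian-based validity
# filtering.

.fit_bounds <- list(log_tau = c(log(1e-6), log(1e3)),
                    eps = c(1e-9, 0.999999))

# Deterministic stratified starting points: midpoints of k equal strata in
# each coordinate, the second coordinate permuted by golden-ratio ranks.
# No RNG is consumed, so fits are reproducible by construction.
.fit_starts <- function(k, bounds = .fit_bounds) {
  lb <- c(bounds$log_tau[1], bounds$eps[1])
  ub <- c(bounds$log_tau[2], bounds$eps[2])
  u1 <- (seq_len(k) - 0.5) / k
  u2 <- (order((seq_len(k) * 0.6180339887498949) %% 1) - 0.5) / k
  cbind(lb[1] + u1 * (ub[1] - lb[1]), lb[2] + u2 * (ub[2] - lb[2]))
}

# Core optimizer on (branching times, s, n). Derivative-free Nelder-Mead
# over x = (log tau, eps) inside bounds, multi-start, polished by a restart
# from the best point; ties broken towards smaller tau.
.fit_bd_core <- function(times, s, n, condition = "n_gt_2",
                         n_restarts = 5, maxit = 400, reltol = 1e-8,
                         bounds = .fit_bounds) {
  ccode <- .cond_code(condition)
  lb <- c(bounds$log_tau[1], bounds$eps[1])
  ub <- c(bounds$log_tau[2], bounds$eps[2])
  nll <- function(x) {
    out <- sum(pmax(lb - x, 0)) + sum(pmax(x - ub, 0))
    if (out > 0) return(1e10 * (1 + out))
    tau <- exp(x[1]); eps <- x[2]
    lam <- tau / (1 + eps)
    ll <- .bd_ll_times_cpp(lam, tau - lam, times, s, n, ccode)
    if (is.finite(ll)) -ll else 1e10
  }
  lam0 <- max((n - 2) / s, 1e-5)
  starts <- rbind(.fit_starts(n_restarts, bounds),
                  c(min(max(log(lam0 * 1.1), lb[1]), ub[1]), 0.1))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    o <- optim(starts[i, ], nll, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = reltol))
    if (is.null(best) || o$value < best$value - 1e-9 ||
        (abs(o$value - best$value) <= 1e-9 && o$par[1] < best$par[1]))
      best <- o
  }
  converged <- FALSE
  for (round in 1:6) {   # polish by restarting until the optimum is stable
    polish <- optim(best$par, nll, method = "Nelder-Mead",
                    control = list(maxit = maxit, reltol = reltol))
    improvement <- best$value - polish$value
    if (polish$value <= best$value) best <- polish
    if (improvement < 1e-6) {
      converged <- TRUE
      break
    }
  }
  tau_hat <- exp(best$par[1]); eps_hat <- best$par[2]
  lambda_hat <- tau_hat / (1 + eps_hat)
  mu_hat <- tau_hat - lambda_hat
  list(tau_hat = tau_hat, eps_hat = eps_hat,
       lambda_hat = lambda_hat, mu_hat = mu_hat,
       r_hat = lambda_hat - mu_hat,
       loglik = -best$value, converged = converged,
       par = best$par)
}

# Central finite-difference Hessian of -loglik in the estimation
# coordinates (log tau, eps) at the optimum; the fit is flagged invalid
# only when the Hessian cannot be inverted or either implied variance is
# nonpositive -- the replicate exclusion rule of the study pipeline.
# Where the optimum is pinned at a box bound (mu = 0 and mu -> lambda are
# substantive boundary hypotheses) the stencil is shifted just inside the
# box so the check remains evaluable; it never raises.
.hessian_valid_core <- function(times, s, n, condition, tau_hat, eps_hat,
                                bounds = .fit_bounds) {
  ccode <- .cond_code(condition)
  h1 <- 1e-4                       # step on log tau ~ relative step on tau
  h2 <- max(1e-4 * eps_hat, 1e-4)
  eb <- bounds$eps; lt <- bounds$log_tau
  lt0 <- min(max(log(tau_hat), lt[1] + h1), lt[2] - h1)
  eps0 <- min(max(eps_hat, eb[1] + h2), eb[2] - h2)
  f <- function(ltau, eps) {
    tau <- exp(ltau)
    lam <- tau / (1 + eps)
    -.bd_ll_times_cpp(lam, tau - lam, times, s, n, ccode)
  }
  f0 <- f(lt0, eps0)
  H <- matrix(NA_real_, 2, 2)
  H[1, 1] <- (f(lt0 + h1, eps0) - 2 * f0 + f(lt0 - h1, eps0)) / h1^2
  H[2, 2] <- (f(lt0, eps0 + h2) - 2 * f0 + f(lt0, eps0 - h2)) / h2^2
  H[1, 2] <- H[2, 1] <-
    (f(lt0 + h1, eps0 + h2) - f(lt0 + h1, eps0 - h2) -
     f(lt0 - h1, eps0 + h2) + f(lt0 - h1, eps0 - h2)) / (4 * h1 * h2)
  if (any(!is.finite(H))) return(FALSE)
  vc <- tryCatch(solve(H), error = function(e) NULL)
  !is.null(vc) && all(is.finite(vc)) && vc[1, 1] > 0 && vc[2, 2] > 0
}

.as_bd_fit <- function(core, n, condition, hessian_valid = NA) {
  structure(list(
    tau_hat = core$tau_hat, eps_hat = core$eps_hat,
    lambda_hat = core$lambda_hat, mu_hat = core$mu_hat,
    r_hat = core$r_hat, loglik = core$loglik,
    converged = core$converged, hessian_valid = hessian_valid,
    n = n, condition = condition), class = "bd_fit")
}

#' Fit a birth-death model to a reconstructed tree
#'
#' Maximizes the branch-product log-likelihood
#' (\code{\link{bd_loglik_branch}}) over the composite parameters turnover
#' \eqn{\tau = \lambda + \mu} and extinction fraction
#' \eqn{\varepsilon = \mu/\lambda}, searched as (log \eqn{\tau},
#' \eqn{\varepsilon}) inside bounds \eqn{\tau \in [10^{-6}, 10^3]},
#' \eqn{\varepsilon \in [10^{-9}, 1)} (the design range of the extinction
#' fraction), then back-transforms to
#' \eqn{(\hat\lambda, \hat\mu)}. The search is a derivative-free
#' Nelder-Mead local search from five stratified starting points plus one
#' data-informed start, with a final polish restart; it is deterministic.
#' Cherry trees (\code{n = 2}) are refused with an error of class
#' \code{"bdbias_nonidentifiable"}: a cherry lacks the information to
#' separate speciation from extinction (its likelihood surface has no
#' interior maximum).
#'
#' @param tree a \code{"recon_tree"} object with \code{n >= 3}.
#' @param condition conditioning of the likelihood: \code{"n_gt_2"}
#'   (default), \code{"survival"} or \code{"none"}.
#' @param hessian run \code{\link{hessian_check}} on the result?
#' @param n_restarts number of stratified restarts.
#' @param maxit,reltol Nelder-Mead control.
#' @return An object of class \code{"bd_fit"} with \code{tau_hat},
#'   \code{eps_hat}, \code{lambda_hat}, \code{mu_hat}, \code{r_hat},
#'   \code{loglik}, \code{converged}, \code{hessian_valid}, \code{n} and
#'   \code{condition}.
#' @export
fit_bd <- function(tree, condition = c("n_gt_2", "survival", "none"),
                   hessian = TRUE, n_restarts = 5, maxit = 400, reltol = 1e-8) {
  condition <- match.arg(condition)
  tree <- as_recon_tree(tree)
  if (tree$n <= 2)
    .stop_nonidentifiable(paste0(
      "cannot jointly estimate lambda and mu on a tree with n <= 2: ",
      "cherry trees lack the information to separate speciation from extinction"))
  core <- .fit_bd_core(tree$branching_times, tree$s, tree$n, condition,
                       n_restarts = n_restarts, maxit = maxit, reltol = reltol)
  fit <- .as_bd_fit(core, tree$n, condition)
  if (hessian) fit <- hessian_check(tree, fit)
  fit
}

#' @export
print.bd_fit <- function(x, ...) {
  cat(sprintf(
    "birth-death fit (%s conditioning, n = %d):\n  lambda = %.6g, mu = %.6g (tau = %.6g, eps = %.6g)\n  loglik = %.6g, converged = %s, hessian_valid = %s\n",
    x$condition, x$n, x$lambda_hat, x$mu_hat, x$tau_hat, x$eps_hat,
    x$loglik, x$converged, x$hessian_valid))
  invisible(x)
}

#' Hessian-based validity check of a birth-death fit
#'
#' Computes a central finite-difference Hessian of the negative
#' log-likelihood in the estimation coordinates \eqn{(\log\tau,
#' \varepsilon)} at the optimum (relative step 1e-4 per coordinate),
#' inverts it, and flags the fit valid only when the inversion succeeds
#' and both implied variances are positive. A fit pinned at a parameter
#' bound is assessed with the stencil shifted just inside the bound and
#' never raises an error. Invalid fits are excluded from study
#' aggregates.
#'
#' @param tree the \code{"recon_tree"} the fit was computed on.
#' @param result a \code{"bd_fit"} from \code{\link{fit_bd}}.
#' @return The fit with \code{hessian_valid} updated.
#' @export
hessian_check <- function(tree, result) {
  tree <- as_recon_tree(tree)
  if (!isTRUE(result$converged)) {
    result$hessian_valid <- FALSE
    return(result)
  }
  result$hessian_valid <- .hessian_valid_core(
    tree$branching_times, tree$s, tree$n, result$condition,
    result$tau_hat, result$eps_hat)
  result
}

# 1-D numeric maximization of the n>2-conditioned Yule likelihood. The
# conditioning term is decreasing in lambda, so the conditioned optimum
# lies below the closed-form (n-2)/s; for very small trees it can sit at
# (numerically) zero.
.yule_mle_cond <- function(n, s, t) {
  upper <- max((n - 2) / s, 1e-8)
  f <- function(l) (n - 2) * log(l) - l * s - log(-expm1(-2 * l * t))
  optimize(f, interval = c(1e-10, upper), maximum = TRUE, tol = 1e-10)$maximum
}

#' Fit a Yule model to a reconstructed tree
#'
#' \code{condition = "none"} or \code{"survival"} use the closed form
#' \eqn{\hat\lambda = (n-2)/s}; \code{condition = "n_gt_2"} maximizes the
#' conditioned likelihood \eqn{(n-1)!\lambda^{n-2}e^{-\lambda s} /
#' (1 - e^{-2\lambda t})} numerically.
#'
#' @param tree a \code{"recon_tree"} object.
#' @param condition \code{"none"}, \code{"survival"} or \code{"n_gt_2"}
#'   (the latter requires \code{n > 2}).
#' @return An object of class \code{"bd_fit"} with \code{mu_hat = 0}.
#' @export
fit_yule <- function(tree, condition = c("none", "survival", "n_gt_2")) {
  condition <- match.arg(condition)
  tree <- as_recon_tree(tree)
  if (condition == "n_gt_2" && tree$n <= 2)
    .stop_nonidentifiable("n > 2 conditioning requires a tree with more than two tips")
  lam <- if (condition == "n_gt_2")
    .yule_mle_cond(tree$n, tree$s, tree$crown_age)
  else yule_mle_closed(tree)
  ll <- yule_loglik(tree, max(lam, 1e-300), condition)
  .as_bd_fit(list(tau_hat = lam, eps_hat = 0, lambda_hat = lam, mu_hat = 0,
                  r_hat = lam, loglik = ll, converged = TRUE),
             tree$n, condition)
}
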
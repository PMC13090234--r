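# Reduced-scale simulation studies: structural bias of survival-only
# conditioning on censored tree sets, Yule bias-correction validation, and
# the birth-death correction study with derived-parameter regressions.

#' Study configuration helper
#'
#' Bundles the knobs of a simulation experiment; used by the command-line
#' wrapper and convenient for keeping runs reproducible.
#'
#' @param experiment one of \code{"structural"}, \code{"yule"}, \code{"bd"}.
#' @param seed master seed; all child seeds derive from it.
#' @param n_trees trees per clade age (structural-bias experiment).
#' @param n_points design points (Yule / birth-death studies).
#' @param out_dir optional output directory for CSV files.
#' @param ... further experiment-specific overrides.
#' @return A list of class \code{"study_config"}.
#' @export
study_config <- function(experiment = c("structural", "yule", "bd"), seed = 1,
                         n_trees = 5000, n_points = 30000, out_dir = NULL, ...) {
  experiment <- match.arg(experiment)
  structure(c(list(experiment = experiment, seed = as.integer(seed),
                   n_trees = n_trees, n_points = n_points, out_dir = out_dir),
              list(...)), class = "study_config")
}

.write_study_csv <- function(df, out_dir, name) {
  if (is.null(out_dir)) return(invisible())
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write.csv(df, file.path(out_dir, name), row.names = FALSE)
  invisible()
}

# fit a batch of simulated trees (branching-time representation)
.fit_batch <- function(sims, keep_idx, condition) {
  k <- length(keep_idx)
  out <- data.frame(row_id = keep_idx, n = sims$n[keep_idx],
                    tau_hat = NA_real_, eps_hat = NA_real_,
                    lambda_hat = NA_real_, mu_hat = NA_real_,
                    loglik = NA_real_, converged = NA, hessian_valid = NA)
  for (j in seq_len(k)) {
    i <- keep_idx[j]
    core <- .fit_bd_core(sims$times[[i]], sims$s[i], sims$n[i], condition)
    out$tau_hat[j] <- core$tau_hat; out$eps_hat[j] <- core$eps_hat
    out$lambda_hat[j] <- core$lambda_hat; out$mu_hat[j] <- core$mu_hat
    out$loglik[j] <- core$loglik; out$converged[j] <- core$converged
    out$hessian_valid[j] <- if (core$converged)
      .hessian_valid_core(sims$times[[i]], sims$s[i], sims$n[i], condition,
                          core$tau_hat, core$eps_hat) else FALSE
  }
  out
}

#' Structural-bias experiment across clade ages
#'
#' Simulates \code{n_trees} crown birth-death trees per clade age at fixed
#' generating rates, censors the set to \code{n > 2}, and fits the
#' birth-death model to every retained tree twice: once with the
#' crown-survival-conditioned likelihood (the conditioning most
#' implementations use, which ignores that cherries were censored) and
#' once with the \code{n > 2}-conditioned likelihood. Reports mean and
#' median \eqn{\hat\lambda, \hat\mu} per age and conditioning (the
#' per-age summary of this experiment is a mean; medians are also emitted
#' for the heavy-tailed small-tree fits), plus the median clade size of
#' the analyzed trees. Both conditionings reuse the same simulated tree
#' set per age.
#'
#' @param ages clade ages.
#' @param n_trees trees per age.
#' @param lambda,mu generating rates.
#' @param seed master seed.
#' @param out_dir optional CSV output directory.
#' @return A \code{data.frame}, one row per age.
#' @export
run_structural_bias_study <- function(ages = c(5, 10, 15, 20, 25, 30), n_trees = 5000,
                       lambda = 0.1, mu = 0.05, seed = 1, out_dir = NULL) {
  stopifnot(n_trees >= 1)
  rows <- vector("list", length(ages))
  for (a in seq_along(ages)) {
    age <- ages[a]
    sims <- .sim_batch(rep(lambda, n_trees), rep(mu, n_trees),
                       rep(age, n_trees), seed, row_offset = (a - 1L) * n_trees)
    keep <- which(sims$status == 2L)
    surv <- .fit_batch(sims, keep, "survival")
    ngt2 <- .fit_batch(sims, keep, "n_gt_2")
    rows[[a]] <- data.frame(
      age = age,
      n_simulated = n_trees,
      n_analyzed = length(keep),
      median_clade_size = median(sims$n[keep]),
      lambda_survival_median = median(surv$lambda_hat),
      mu_survival_median = median(surv$mu_hat),
      lambda_ngt2_median = median(ngt2$lambda_hat),
      mu_ngt2_median = median(ngt2$mu_hat),
      lambda_survival_mean = mean(surv$lambda_hat),
      mu_survival_mean = mean(surv$mu_hat),
      lambda_ngt2_mean = mean(ngt2$lambda_hat),
      mu_ngt2_mean = mean(ngt2$mu_hat))
  }
  out <- do.call(rbind, rows)
  .write_study_csv(out, out_dir, "structural_bias_by_age.csv")
  out
}

#' Yule bias-correction validation study
#'
#' Latin-hypercube design over clade age and speciation rate, one crown
#' Yule tree per design point; trees with \code{n <= 2} are discarded (not
#' resampled). Rates are estimated with the \code{n > 2}-conditioned Yule
#' likelihood, then regressed (Huber) on their generating values before
#' and after the \eqn{(n-1)/(n-2)} correction; optionally the symbolic
#' regression search is run on the same estimates.
#'
#' @param n_points number of design points.
#' @param seed master seed.
#' @param age_range,lambda_range design ranges.
#' @param symreg run the symbolic-regression search?
#' @param alpha_max penalty-grid upper end for the search.
#' @param n_grid alpha grid size.
#' @param max_depth maximum expression depth for the search; the default
#'   (3) spans a single operator in the dimensionless factor, which covers
#'   every candidate correction the method is expected to weigh while
#'   excluding two-operator factors that can overfit sample-specific tilt.
#' @param out_dir optional CSV output directory.
#' @return A list with \code{design}, \code{estimates} (one row per
#'   retained tree), \code{stats} (slopes/intercepts), \code{symreg} (the
#'   search output or \code{NULL}) and \code{counts}.
#' @export
run_yule_validation <- function(n_points = 30000, seed = 1,
                                age_range = c(0, 5), lambda_range = c(0, 0.5),
                                symreg = TRUE, alpha_max = 0.02, n_grid = 5000,
                                max_depth = 3, out_dir = NULL) {
  design <- lhs_design(n_points, list(age = age_range, lambda = lambda_range),
                       seed = seed)
  sims <- .sim_batch(design$lambda, rep(0, n_points), design$age, seed)
  keep <- which(sims$status == 2L)
  est <- data.frame(
    row_id = keep,
    age = design$age[keep],
    lambda_true = design$lambda[keep],
    n = sims$n[keep],
    s = sims$s[keep])
  est$lambda_hat <- vapply(seq_along(keep), function(j)
    .yule_mle_cond(est$n[j], est$s[j], est$age[j]), numeric(1))
  est$lambda_corr <- correct_lambda(est$lambda_hat, est$n)
  raw_line <- huber_line(est$lambda_true, est$lambda_hat)
  corr_line <- huber_line(est$lambda_true, est$lambda_corr)
  stats <- data.frame(
    quantity = c("lambda_uncorrected", "lambda_corrected"),
    slope = c(raw_line$slope, corr_line$slope),
    intercept = c(raw_line$intercept, corr_line$intercept),
    n = length(keep))
  sr <- NULL
  if (symreg) {
    dat <- data.frame(theta_hat = est$lambda_hat, theta_true = est$lambda_true,
                      n = as.numeric(est$n))
    sr <- symreg_search(dat, target = "lambda", alpha_max = alpha_max,
                        max_depth = max_depth, n_grid = n_grid)
  }
  .write_study_csv(est, out_dir, "yule_validation_estimates.csv")
  .write_study_csv(stats, out_dir, "yule_validation_slopes.csv")
  if (!is.null(sr)) .write_study_csv(sr$ranking, out_dir, "yule_symreg_ranking.csv")
  list(design = design, estimates = est, stats = stats, symreg = sr,
       counts = list(n_design = n_points, n_retained = length(keep)))
}

#' Derived-parameter regression statistics
#'
#' From a table of birth-death estimates and generating values, applies
#' the recommended corrections and fits Huber regressions of: corrected
#' speciation and extinction rates on their generating values; corrected
#' turnover (\eqn{\lambda_{corr}+\mu_{corr}}) on true turnover; net
#' diversification computed as \eqn{\lambda_{corr}-\mu_{corr}} on true net
#' diversification; net diversification corrected directly as
#' \eqn{(\hat\lambda-\hat\mu)(n/(n-1)+\hat\varepsilon)}; and
#' expectation-recalibrated turnover, where each corrected rate is first
#' linearly recalibrated by inverting its regression on the generating
#' values.
#'
#' @param est a \code{data.frame} with columns \code{lambda_true},
#'   \code{mu_true}, \code{lambda_hat}, \code{mu_hat}, \code{eps_hat},
#'   \code{n}.
#' @return A \code{data.frame} of slopes and intercepts, one row per
#'   quantity.
#' @export
derived_parameter_stats <- function(est) {
  tau_true <- est$lambda_true + est$mu_true
  r_true <- est$lambda_true - est$mu_true
  lc <- correct_lambda(est$lambda_hat, est$n)
  mc <- correct_mu(est$mu_hat, est$eps_hat, est$n)
  rc <- correct_netdiv(est$lambda_hat - est$mu_hat, est$eps_hat, est$n)
  map_l <- expectation_recalibrate(lc, est$lambda_true, tag = "lambda")
  map_m <- expectation_recalibrate(mc, est$mu_true, tag = "mu")
  lp <- apply_map(lc, map_l)
  mp <- apply_map(mc, map_m)
  lines <- list(
    lambda_corrected = huber_line(est$lambda_true, lc),
    mu_corrected = huber_line(est$mu_true, mc),
    turnover_corrected = huber_line(tau_true, lc + mc),
    turnover_recalibrated = huber_line(tau_true, lp + mp),
    netdiv_from_corrected = huber_line(r_true, lc - mc),
    netdiv_recalibrated = huber_line(r_true, lp - mp),
    netdiv_direct_correction = huber_line(r_true, rc))
  data.frame(
    quantity = names(lines),
    slope = vapply(lines, `[[`, numeric(1), "slope"),
    intercept = vapply(lines, `[[`, numeric(1), "intercept"),
    n = nrow(est), row.names = NULL)
}

#' Birth-death bias-correction study
#'
#' Latin-hypercube design over clade age, speciation rate and extinction
#' fraction (extinction rate \code{mu = lambda * epsilon}); one crown
#' birth-death tree per design point; censoring to \code{n > 2}; maximum
#' likelihood in the (turnover, extinction fraction) parameterization with
#' the \code{n > 2}-conditioned likelihood; exclusion of fits whose
#' Hessian-implied variances are not both positive; corrections and
#' derived-parameter Huber regressions
#' (\code{\link{derived_parameter_stats}});
#' optionally the symbolic-regression searches for the speciation and
#' extinction corrections.
#'
#' @param n_points number of design points.
#' @param seed master seed.
#' @param age_range,lambda_range,eps_range design ranges.
#' @param symreg run the symbolic-regression searches?
#' @param retain which fits enter the aggregates: \code{"converged"}
#'   (default) keeps every converged fit, including boundary (zero-rate
#'   and near-critical) estimates; \code{"hessian_valid"} additionally
#'   drops fits whose Hessian-implied variances are not both positive.
#' @param alpha_max_lambda,alpha_max_mu penalty-grid upper ends.
#' @param n_grid alpha grid size.
#' @param max_depth maximum expression depth.
#' @param out_dir optional CSV output directory.
#' @param progress print progress every 2000 fits?
#' @return A list with \code{design}, \code{estimates} (all fitted trees),
#'   \code{retained} (converged, Hessian-valid), \code{stats}
#'   (\code{derived_parameter_stats} on the retained set), \code{symreg_lambda},
#'   \code{symreg_mu} and \code{counts}.
#' @export
run_bd_study <- function(n_points = 30000, seed = 1,
                         age_range = c(0, 10), lambda_range = c(0, 1),
                         eps_range = c(0, 1), symreg = TRUE,
                         retain = c("converged", "hessian_valid"),
                         alpha_max_lambda = 1e-3, alpha_max_mu = 0.1,
                         n_grid = 5000, max_depth = 3, out_dir = NULL,
                         progress = FALSE) {
  retain <- match.arg(retain)
  design <- lhs_design(n_points, list(age = age_range, lambda = lambda_range,
                                      epsilon = eps_range), seed = seed)
  sims <- .sim_batch(design$lambda, design$mu, design$age, seed,
                     until_survival = TRUE)
  keep <- which(sims$status == 2L)
  fits <- .fit_batch(sims, keep, "n_gt_2")
  est <- cbind(
    data.frame(age = design$age[keep],
               lambda_true = design$lambda[keep],
               mu_true = design$mu[keep]),
    fits)
  sel <- if (retain == "hessian_valid") est$converged & est$hessian_valid
         else est$converged
  retained <- est[sel, , drop = FALSE]
  stats <- derived_parameter_stats(retained)
  sr_l <- sr_m <- NULL
  if (symreg) {
    dat_l <- data.frame(theta_hat = retained$lambda_hat,
                        theta_true = retained$lambda_true,
                        n = as.numeric(retained$n), eps_hat = retained$eps_hat)
    sr_l <- symreg_search(dat_l, target = "lambda",
                          alpha_max = alpha_max_lambda,
                          max_depth = max_depth, n_grid = n_grid)
    dat_m <- data.frame(theta_hat = retained$mu_hat,
                        theta_true = retained$mu_true,
                        n = as.numeric(retained$n), eps_hat = retained$eps_hat)
    sr_m <- symreg_search(dat_m, target = "mu", alpha_max = alpha_max_mu,
                          max_depth = max_depth, n_grid = n_grid, top_k = 15)
  }
  .write_study_csv(est, out_dir, "bd_study_estimates.csv")
  .write_study_csv(stats, out_dir, "bd_study_slopes.csv")
  if (!is.null(sr_l)) .write_study_csv(sr_l$ranking, out_dir, "bd_symreg_lambda.csv")
  if (!is.null(sr_m)) .write_study_csv(sr_m$ranking, out_dir, "bd_symreg_mu.csv")
  list(design = design, estimates = est, retained = retained, stats = stats,
       symreg_lambda = sr_l, symreg_mu = sr_m,
       counts = list(n_design = n_points, n_usable = length(keep),
                     n_converged = sum(fits$converged),
                     n_hessian_valid = sum(fits$converged & fits$hessian_valid),
                     n_retained = nrow(retained)))
}
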
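#' Latin-hypercube experiment design
#'
#' Stratified design: each variable has exactly one sample in each of
#' \code{n_points} equal-width strata of its range. If the ranges contain
#' both \code{lambda} and \code{epsilon} (and no \code{mu}), an extinction
#' rate column \code{mu = lambda * epsilon} is appended, matching the
#' birth-death study design in which the extinction rate is derived from
#' the sampled extinction fraction.
#'
#' @param n_points number of design points, >= 1.
#' @param ranges named list of \code{c(lo, hi)} ranges, one per variable.
#' @param seed integer seed; the same seed reproduces the same table.
#' @return A \code{data.frame} with one column per variable (plus
#'   \code{mu} where applicable) and attributes \code{scheme} and
#'   \code{seed}.
#' @examples
#' lhs_design(4, list(lambda = c(0, 1)), seed = 1)
#' @export
lhs_design <- function(n_points, ranges, seed) {
  stopifnot(n_points >= 1, length(ranges) >= 1)
  if (is.null(names(ranges)) || any(!nzchar(names(ranges))))
    stop("'ranges' must be a named list")
  for (nm in names(ranges)) {
    rg <- ranges[[nm]]
    if (length(rg) != 2 || !all(is.finite(rg)) || rg[1] >= rg[2])
      stop(sprintf("range for '%s' must be c(lo, hi) with lo < hi", nm))
  }
  set.seed(as.integer(seed))
  u <- lhs::randomLHS(n_points, length(ranges))
  out <- as.data.frame(mapply(function(j, nm) {
    rg <- ranges[[nm]]
    rg[1] + u[, j] * (rg[2] - rg[1])
  }, seq_along(ranges), names(ranges), SIMPLIFY = FALSE),
  col.names = names(ranges))
  names(out) <- names(ranges)
  if (all(c("lambda", "epsilon") %in% names(out)) && !("mu" %in% names(out)))
    out$mu <- out$lambda * out$epsilon
  attr(out, "scheme") <- "latin-hypercube"
  attr(out, "seed") <- as.integer(seed)
  out
}

# ---------------------------------------------------------------------------

.build_complete_phylo <- function(parent, birth, end, event) {
  # lineage records from the simulator (0-based parents; -1 = crown root)
  L <- length(parent)
  is_tip <- event != 2L
  ntip <- sum(is_tip)
  tip_id <- cumsum(is_tip)
  int_id <- cumsum(!is_tip)
  node_of <- ifelse(is_tip, tip_id, ntip + 1L + int_id)
  parent1 <- parent + 1L                   # 1-based; 0 = crown root
  parent_node <- ifelse(parent1 == 0L, ntip + 1L,
                        ntip + 1L + int_id[pmax(parent1, 1L)])
  phy <- list(edge = cbind(parent_node, node_of, deparse.level = 0),
              edge.length = end - birth,
              tip.label = paste0("t", seq_len(ntip)),
              Nnode = 1L + sum(!is_tip))
  class(phy) <- "phylo"
  attr(phy, "extant") <- phy$tip.label[event[is_tip] == 0L]
  phy
}

#' Simulate a crown-start constant-rate birth-death tree
#'
#' Event-driven (Gillespie) forward simulation from two lineages at the
#' crown for a fixed duration \code{age}: waiting times are exponential
#' with total rate \code{n_alive * (lambda + mu)} and each event is a
#' speciation with probability \code{lambda / (lambda + mu)}. The complete
#' tree (extinct lineages included) is recorded; the reconstructed tree is
#' obtained by pruning extinct subtrees. The censoring status is
#' \code{"extinct"} if either crown daughter has no extant descendant,
#' \code{"cherry"} if the crown survives with exactly two extant tips, and
#' \code{"usable"} otherwise (\code{n > 2}).
#'
#' @param params a \code{\link{bd_params}} object.
#' @param age crown age (simulation duration), > 0.
#' @param seed optional integer seed.
#' @param keep_complete keep the complete tree (and build phylo objects)?
#'   Set \code{FALSE} for large batch runs where only the reconstructed
#'   branching times are needed.
#' @return An object of class \code{"sim_outcome"}: a list with
#'   \code{status}, \code{n_extant}, \code{branching_times} (reconstructed,
#'   descending; \code{NULL} if the crown died), \code{s},
#'   \code{complete_tree} (a \code{"phylo"} with attribute \code{"extant"},
#'   or \code{NULL}), \code{reconstructed_tree} (a \code{"recon_tree"} or
#'   \code{NULL}) and \code{seed}.
#' @export
simulate_crown_tree <- function(params, age, seed = NULL, keep_complete = TRUE) {
  params <- .as_bd_params(params)
  if (!is.numeric(age) || age <= 0) stop("age must be positive")
  if (!is.null(seed)) set.seed(as.integer(seed))
  res <- .sim_crown_cpp(params$lambda, params$mu, age, 2L, keep_complete)
  status <- c("extinct", "cherry", "usable")[res$status + 1L]
  complete <- NULL
  recon <- NULL
  if (keep_complete) {
    complete <- .build_complete_phylo(res$parent, res$birth, res$end, res$event)
    if (res$status > 0L)
      recon <- prune_extinct(complete, extant = attr(complete, "extant"))
  }
  structure(list(
    status = status,
    n_extant = res$n_extant,
    branching_times = if (res$status > 0L) res$times else NULL,
    s = res$s,
    complete_tree = complete,
    reconstructed_tree = recon,
    seed = seed
  ), class = "sim_outcome")
}

#' @export
print.sim_outcome <- function(x, ...) {
  cat(sprintf("birth-death simulation outcome: status = %s, n_extant = %d\n",
              x$status, x$n_extant))
  invisible(x)
}

#' Prune extinct lineages from a complete tree
#'
#' Removes all extinct subtrees and suppresses the resulting degree-2 nodes
#' (their branch lengths are summed), yielding the reconstructed,
#' extant-only, ultrametric tree. Returns \code{NULL} when the crown did
#' not survive, i.e. when either daughter lineage of the root has no extant
#' descendant -- the crown age of the reconstructed tree is then not the
#' crown age of the process and the conditioning formulas do not apply.
#'
#' @param complete_tree a \code{"phylo"} complete tree.
#' @param extant tip labels (or a logical vector over tips) marking extant
#'   tips; by default tips at age 0 (within tolerance) are taken as extant.
#' @param tol relative age tolerance used when inferring extant tips.
#' @return A \code{"recon_tree"} object, or \code{NULL} if the crown did
#'   not survive.
#' @export
prune_extinct <- function(complete_tree, extant = NULL, tol = 1e-8) {
  phy <- complete_tree
  if (!inherits(phy, "phylo")) stop("'complete_tree' must be a \"phylo\" object")
  ntip <- length(phy$tip.label)
  depth <- ape::node.depth.edgelength(phy)
  height <- max(depth[seq_len(ntip)])
  if (is.null(extant)) extant <- attr(phy, "extant")
  if (is.null(extant))
    extant <- phy$tip.label[abs(height - depth[seq_len(ntip)]) <= tol * height]
  if (is.logical(extant)) extant <- phy$tip.label[extant]
  if (!length(extant)) return(NULL)
  root <- ntip + 1L
  kids <- phy$edge[phy$edge[, 1] == root, 2]
  side_ok <- vapply(kids, function(k) {
    tips <- if (k <= ntip) phy$tip.label[k]
            else ape::extract.clade(phy, k)$tip.label
    any(tips %in% extant)
  }, logical(1))
  if (!all(side_ok)) return(NULL)
  drop <- setdiff(phy$tip.label, extant)
  pruned <- if (length(drop)) ape::drop.tip(phy, drop, collapse.singles = TRUE) else phy
  as_recon_tree(pruned, tol = tol)
}

#' Censor a list of simulation outcomes
#'
#' \code{rule = "survival"} keeps crown-surviving outcomes (cherry and
#' usable); \code{rule = "n_gt_2"} additionally drops cherry trees. Points
#' failing the rule are discarded, not resampled: the study protocol draws
#' one tree per design point.
#'
#' @param outcomes a list of \code{"sim_outcome"} objects.
#' @param rule \code{"survival"} or \code{"n_gt_2"}.
#' @return The retained sublist.
#' @export
apply_censoring <- function(outcomes, rule = c("survival", "n_gt_2")) {
  rule <- match.arg(rule)
  keep <- switch(rule,
    survival = c("cherry", "usable"),
    n_gt_2 = "usable")
  Filter(function(o) o$status %in% keep, outcomes)
}

# Fast batch simulation used by the study pipeline: only status, tip count,
# total edge length and reconstructed branching times are kept. Child seeds
# are derived deterministically from (master seed, row id). With
# until_survival = TRUE each design point is redrawn until the crown
# survives (the tree returned is conditioned on crown survival); cherries
# are still reported as such and are censored downstream.
.sim_batch <- function(lambda, mu, age, seed, row_offset = 0L,
                       until_survival = FALSE, max_attempts = 100000L) {
  k <- length(lambda)
  status <- integer(k); n <- integer(k); s <- numeric(k)
  times <- vector("list", k)
  for (i in seq_len(k)) {
    set.seed(.child_seed(seed, i + row_offset))
    res <- .sim_crown_cpp(lambda[i], mu[i], age[i], 2L, FALSE)
    if (until_survival) {
      att <- 1L
      while (res$status == 0L && att < max_attempts) {
        res <- .sim_crown_cpp(lambda[i], mu[i], age[i], 2L, FALSE)
        att <- att + 1L
      }
    }
    status[i] <- res$status
    n[i] <- res$n_extant
    s[i] <- res$s
    times[[i]] <- res$times
  }
  list(status = status, n = n, s = s, times = times)
}
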
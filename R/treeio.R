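#' Birth-death model parameters
#'
#' Container for a speciation rate \code{lambda} and extinction rate
#' \code{mu}, with the derived quantities used throughout the package: net
#' diversification \code{r = lambda - mu}, extinction fraction
#' \code{epsilon = mu / lambda} (undefined when \code{lambda = 0}) and
#' turnover \code{tau = lambda + mu}. Rates are events per lineage per unit
#' time.
#'
#' @param lambda speciation rate, >= 0.
#' @param mu extinction rate, >= 0.
#' @return An object of class \code{"bd_params"}.
#' @examples
#' bd_params(0.1, 0.05)
#' @export
bd_params <- function(lambda, mu) {
  stopifnot(length(lambda) == 1L, length(mu) == 1L)
  if (!is.finite(lambda) || !is.finite(mu) || lambda < 0 || mu < 0)
    stop("lambda and mu must be finite and nonnegative")
  structure(list(
    lambda = lambda, mu = mu,
    r = lambda - mu,
    epsilon = if (lambda > 0) mu / lambda else NA_real_,
    tau = lambda + mu
  ), class = "bd_params")
}

.as_bd_params <- function(params) {
  if (inherits(params, "bd_params")) return(params)
  if (is.list(params) && all(c("lambda", "mu") %in% names(params)))
    return(bd_params(params$lambda, params$mu))
  stop("'params' must be a bd_params object (see bd_params())")
}

#' @export
print.bd_params <- function(x, ...) {
  cat(sprintf(
    "birth-death parameters: lambda = %g, mu = %g (r = %g, eps = %g, tau = %g)\n",
    x$lambda, x$mu, x$r, x$epsilon, x$tau))
  invisible(x)
}

# ---------------------------------------------------------------------------

#' Build a reconstructed-tree object from an ape phylogeny
#'
#' Validates that a tree is rooted, strictly bifurcating, has branch lengths
#' on every edge and is ultrametric (all tips at age 0 within
#' \code{tol * crown age}; tip ages within tolerance are snapped to exactly
#' 0), then records the quantities the likelihood functions consume: tip
#' count \code{n}, internal node count \code{m = n - 1}, total edge length
#' \code{s}, crown age, branching times (node ages, descending) and the 2m
#' branch segments as (rootward age, tipward age) pairs. Ages are measured
#' backward from the present, tips at age 0.
#'
#' @param phy an object of class \code{"phylo"}.
#' @param tol relative ultrametricity tolerance (default 1e-8 of crown age).
#' @return An object of class \code{"recon_tree"}.
#' @export
as_recon_tree <- function(phy, tol = 1e-8) {
  if (inherits(phy, "recon_tree")) return(phy)
  if (!inherits(phy, "phylo")) stop("'phy' must be a \"phylo\" object")
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  if (is.null(phy$edge.length))
    stop("tree has no branch lengths; branch lengths are mandatory")
  if (anyNA(phy$edge.length) || any(!is.finite(phy$edge.length)))
    stop("missing or non-finite branch length on at least one edge")
  if (any(phy$edge.length < 0)) stop("negative branch length")
  n <- length(phy$tip.label)
  if (n < 2) stop("tree must have at least two tips")
  if (phy$Nnode != n - 1L)
    stop("tree is not strictly bifurcating (polytomy or singleton node present)")
  depth <- ape::node.depth.edgelength(phy)
  crown_age <- max(depth[seq_len(n)])
  if (crown_age <= 0) stop("tree has zero height")
  age <- crown_age - depth
  bad <- which(abs(age[seq_len(n)]) > tol * crown_age)
  if (length(bad))
    stop(sprintf("tree is not ultrametric: tip '%s' is at age %.6g (tolerance %.3g)",
                 phy$tip.label[bad[1]], age[bad[1]], tol * crown_age))
  age[seq_len(n)] <- 0
  rootward <- age[phy$edge[, 1]]
  tipward <- age[phy$edge[, 2]]
  if (any(rootward < tipward))
    stop("branch with rootward age below tipward age")
  internal_ages <- age[(n + 1L):(2L * n - 1L)]
  structure(list(
    phylo = phy,
    n = n,
    m = n - 1L,
    s = sum(rootward - tipward),
    crown_age = age[n + 1L],
    branching_times = sort(internal_ages, decreasing = TRUE),
    branch_rootward = rootward,
    branch_tipward = tipward,
    tip_labels = phy$tip.label
  ), class = "recon_tree")
}

#' @export
print.recon_tree <- function(x, ...) {
  cat(sprintf(
    "reconstructed tree: n = %d tips, m = %d internal nodes, crown age = %g, s = %g\n",
    x$n, x$m, x$crown_age, x$s))
  invisible(x)
}

#' Parse a Newick string into a reconstructed tree
#'
#' The string must describe a single rooted, strictly bifurcating,
#' ultrametric tree with a branch length on every edge. Polytomies, missing
#' branch lengths and non-ultrametric trees are rejected with an explicit
#' message.
#'
#' @param text a Newick string, e.g. \code{"((B:1,C:1):1,A:2);"}.
#' @param tol relative ultrametricity tolerance.
#' @return A \code{"recon_tree"} object.
#' @examples
#' tr <- parse_newick("((B:1,C:1):1,A:2);")
#' tree_summaries(tr)
#' @export
parse_newick <- function(text, tol = 1e-8) {
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy)) stop("could not parse Newick string")
  if (inherits(phy, "multiPhylo")) {
    if (length(phy) != 1L) stop("expected a single tree")
    phy <- phy[[1L]]
  }
  as_recon_tree(phy, tol = tol)
}

#' Read trees from a Newick file
#'
#' One tree per line; blank lines and lines starting with \code{#} are
#' ignored.
#'
#' @param file path to a Newick file.
#' @param tol relative ultrametricity tolerance.
#' @return A list of \code{"recon_tree"} objects.
#' @export
read_newick_trees <- function(file, tol = 1e-8) {
  lines <- readLines(file, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(lines, parse_newick, tol = tol)
}

#' Serialize a reconstructed tree to Newick
#'
#' Round-trip safe: parsing the returned string reproduces branch ages
#' within 1e-10.
#'
#' @param tree a \code{"recon_tree"} or \code{"phylo"} object.
#' @param file optional path; if given the string is also written there.
#' @param digits number of significant digits for branch lengths.
#' @return The Newick string, invisibly when \code{file} is given.
#' @export
write_newick <- function(tree, file = NULL, digits = 15) {
  phy <- if (inherits(tree, "recon_tree")) tree$phylo else tree
  txt <- ape::write.tree(phy, digits = digits)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Summary quantities of a reconstructed tree
#'
#' @param tree a \code{"recon_tree"} object (or anything
#'   \code{\link{as_recon_tree}} accepts).
#' @return A list with \code{n}, \code{m}, \code{s}, \code{crown_age} and
#'   \code{branching_times} (node ages, descending; first element is the
#'   crown age).
#' @export
tree_summaries <- function(tree) {
  tree <- as_recon_tree(tree)
  tree[c("n", "m", "s", "crown_age", "branching_times")]
}
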
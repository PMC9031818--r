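#' Read a sample of rooted, dated trees
#'
#' Reads Newick or NEXUS (TREES block, translate tables supported) files into
#' a `multiPhylo` tree sample, preserving file order. Tree samples are used
#' to propagate phylogenetic uncertainty: every downstream statistic is
#' computed per tree and then aggregated across the sample.
#'
#' @param path tree file.
#' @param format `"auto"` (sniff for a `#NEXUS` header), `"newick"`, or
#'   `"nexus"`.
#' @return A `multiPhylo` object (even for a single tree).
#' @export
read_tree_sample <- function(path, format = c("auto", "newick", "nexus")) {
  format <- match.arg(format)
  if (format == "auto") {
    head <- readLines(path, n = 1L, warn = FALSE)
    format <- if (grepl("^\\s*#NEXUS", head, ignore.case = TRUE))
      "nexus" else "newick"
  }
  trees <- if (format == "nexus") ape::read.nexus(path) else ape::read.tree(path)
  if (is.null(trees))
    stop("could not parse any tree from '", path, "'", call. = FALSE)
  trees <- as_tree_sample(trees)
  for (i in seq_along(trees)) {
    if (is.null(trees[[i]]$edge.length))
      stop("tree ", i, " in '", path, "' has no branch lengths", call. = FALSE)
    if (any(trees[[i]]$edge.length < 0))
      stop("tree ", i, " in '", path, "' has negative branch lengths",
           call. = FALSE)
  }
  trees
}

#' Coerce a phylo or list of trees to a multiPhylo sample
#' @param trees a `phylo`, `multiPhylo`, or list of `phylo` objects.
#' @return A `multiPhylo`.
#' @export
as_tree_sample <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!inherits(trees, "multiPhylo")) {
    stopifnot(all(vapply(trees, inherits, logical(1L), "phylo")))
    class(trees) <- "multiPhylo"
  }
  trees
}

#' Prune a tree to a set of tips
#'
#' Drops all other tips and suppresses the resulting unifurcations by
#' summing branch lengths, so patristic distances among the kept tips are
#' unchanged. Tips requested but absent are a fatal error (silent tip loss
#' corrupts comparative analyses); names are compared exactly after
#' whitespace trimming.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param keep character vector of tip labels to retain.
#' @return The pruned `phylo`.
#' @export
prune_tree <- function(tree, keep) {
  keep <- trimws(keep)
  tree$tip.label <- trimws(tree$tip.label)
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing) > 0L)
    stop("tip(s) missing from tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (length(keep) == length(tree$tip.label)) return(tree)
  ape::keep.tip(tree, keep)
}

#' Brownian-motion covariance matrix of a tree
#'
#' The covariance structure implied by Brownian motion on a rooted tree with
#' branch lengths: `C[i, j]` is the shared root-to-MRCA path length of tips
#' `i` and `j`, and `C[i, i]` the root-to-tip distance. For ultrametric
#' (dated) trees the diagonal is constant.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param tip_order optional character vector (a permutation of the tip
#'   labels) fixing the row/column order.
#' @return A symmetric positive semi-definite matrix with tip-label dimnames.
#' @export
phylo_vcv <- function(tree, tip_order = NULL) {
  if (!ape::is.rooted(tree))
    stop("tree must be rooted to define a BM covariance", call. = FALSE)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  C <- ape::vcv(tree)
  if (!is.null(tip_order)) {
    if (!setequal(tip_order, rownames(C)) ||
        length(tip_order) != nrow(C))
      stop("tip_order must be a permutation of the tree's tip labels",
           call. = FALSE)
    C <- C[tip_order, tip_order, drop = FALSE]
  }
  C
}

# Precompute the GLS quantities shared by K, the permutation test, and the
# phylogenetic correlation: C^-1, the row-sum vector w = C^-1 1, and
# s = 1' C^-1 1. With pseudo = TRUE a rank-deficient C (duplicate rows from
# zero-length terminal branches) is handled by a tolerance-based
# pseudo-inverse instead of an error.
gls_prep <- function(C, pseudo = FALSE) {
  if (anyDuplicated(round(C, 12L)) > 0L)
    warning("covariance matrix has duplicate rows (zero-length terminal ",
            "branches?); GLS may be singular", call. = FALSE)
  singular <- function() {
    if (!pseudo)
      stop("BM covariance matrix is computationally singular; ",
           "set pseudo = TRUE to use a pseudo-inverse", call. = FALSE)
    pinv(C)
  }
  Cinv <- tryCatch({
    ch <- chol(C)
    # guard against near-zero pivots that chol() lets through
    if (min(diag(ch)) < 1e-6 * max(diag(ch))) singular()
    else chol2inv(ch)
  }, error = function(e) singular())
  w <- rowSums(Cinv)
  list(C = C, Cinv = Cinv, w = w, s = sum(w), n = nrow(C),
       trC = sum(diag(C)))
}

# Align a named trait vector with a covariance matrix (or check lengths when
# unnamed). Whitespace-trimmed exact matching; mismatch is fatal.
align_trait <- function(x, C) {
  if (!is.null(names(x)) && !is.null(rownames(C))) {
    names(x) <- trimws(names(x))
    missing <- setdiff(rownames(C), names(x))
    if (length(missing) > 0L)
      stop("trait values missing for tip(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    x <- x[rownames(C)]
  } else if (length(x) != nrow(C)) {
    stop("trait length (", length(x), ") does not match matrix dimension (",
         nrow(C), ")", call. = FALSE)
  }
  unname(x)
}
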
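#' Phylogenetic Pearson correlation under Brownian motion
#'
#' The Pearson correlation of two traits after accounting for the
#' tree-implied covariance: with GLS residuals `dx = x - ax 1` and
#' `dy = y - ay 1`, the evolutionary (co)variances are
#' `sxy = dx' C^-1 dy / (n - 1)` (and analogously `sxx`, `syy`), and
#' `r = sxy / sqrt(sxx syy)`. Equivalent to the correlation through the
#' origin of phylogenetically independent contrasts. The `n - 1` (REML-style)
#' denominator matches the mean-square convention of [blomberg_k()]; it
#' cancels in `r` itself.
#'
#' @param x,y trait vectors, named by tip or aligned with `C`.
#' @param C BM covariance matrix from [phylo_vcv()].
#' @param pseudo use a pseudo-inverse if `C` is singular.
#' @return Correlation in `[-1, 1]`.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' phylo_pearson(c(A = 1, B = 2, C = 4), c(A = 3, B = 1, C = 2),
#'               phylo_vcv(tr))
#' @export
phylo_pearson <- function(x, y, C, pseudo = FALSE) {
  x <- align_trait(x, C)
  y <- align_trait(y, C)
  g <- gls_prep(C, pseudo = pseudo)
  dx <- x - sum(g$w * x) / g$s
  dy <- y - sum(g$w * y) / g$s
  sxx <- drop(crossprod(dx, g$Cinv %*% dx))
  syy <- drop(crossprod(dy, g$Cinv %*% dy))
  if (sxx <= 0 || syy <= 0)
    stop("zero evolutionary variance in one of the traits", call. = FALSE)
  sxy <- drop(crossprod(dx, g$Cinv %*% dy))
  r <- sxy / sqrt(sxx * syy)
  max(-1, min(1, r))
}

#' Two-sided test of a correlation against zero
#'
#' Student-t transform of a correlation estimate:
#' `t = r sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of freedom,
#' testing the null that the correlation is zero. Applied in this package to
#' the posterior-mean correlation over a tree sample.
#'
#' @param r correlation estimate in `[-1, 1]`.
#' @param n number of taxa behind the estimate.
#' @return List with `statistic` (t), `df`, and `p`.
#' @export
correlation_test <- function(r, n) {
  stopifnot(n >= 3L, abs(r) <= 1)
  if (abs(r) == 1) {
    warning("|r| = 1: p reported as the limiting value 0", call. = FALSE)
    return(list(statistic = sign(r) * Inf, df = n - 2L, p = 0))
  }
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(statistic = t, df = n - 2L, p = 2 * stats::pt(-abs(t), df = n - 2))
}

#' Phylogenetic correlation of a trait pair over a tree sample
#'
#' Computes the phylogenetic Pearson correlation on every tree of a sample,
#' giving a (posterior) sample of the correlation that propagates
#' phylogenetic uncertainty. The point estimate is the posterior mean of the
#' per-tree correlations, the 95% interval is the equal-tail 2.5%/97.5%
#' quantile interval over trees, and the p value comes from
#' [correlation_test()] applied to the posterior mean with `n - 2` degrees
#' of freedom.
#'
#' @param trait_x,trait_y names of the two trait columns.
#' @param table trait table (`data.frame` with `language_id` + traits).
#' @param trees a `multiPhylo` sample.
#' @param level interval coverage (default 0.95).
#' @param pseudo passed to the GLS routines.
#' @return Object of class `"correlation_result"`: list with `pair`,
#'   per-tree `r`, `r_mean`, `ci` (length 2), `p`, `df`, `n`.
#' @export
correlate_over_sample <- function(trait_x, trait_y, table, trees,
                                  level = 0.95, pseudo = FALSE) {
  trees <- as_tree_sample(trees)
  for (tr in c(trait_x, trait_y))
    if (!tr %in% names(table))
      stop("trait '", tr, "' not in table", call. = FALSE)
  x <- stats::setNames(table[[trait_x]], table$language_id)
  y <- stats::setNames(table[[trait_y]], table$language_id)
  r <- vapply(trees, function(tree) {
    ptree <- prune_tree(tree, names(x))
    phylo_pearson(x, y, phylo_vcv(ptree), pseudo = pseudo)
  }, numeric(1L))
  r_mean <- mean(r)
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(r, c(alpha, 1 - alpha)))
  n <- length(x)
  test <- correlation_test(r_mean, n)
  structure(
    list(pair = c(trait_x, trait_y), r = unname(r), r_mean = r_mean,
         ci = ci, p = test$p, df = test$df, n = n),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf(
    "Phylogenetic correlation %s ~ %s over %d tree(s): r = %.3f [%.3f, %.3f], p = %.3g (df = %d)\n",
    x$pair[1L], x$pair[2L], length(x$r), x$r_mean, x$ci[1L], x$ci[2L],
    x$p, x$df))
  invisible(x)
}

#' @export
as.data.frame.correlation_result <- function(x, ...) {
  data.frame(pair = paste(x$pair, collapse = ":"),
             tree_index = seq_along(x$r), r = x$r, stringsAsFactors = FALSE)
}
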
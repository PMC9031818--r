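#' Generalized least squares estimate of the root state
#'
#' The GLS (phylogenetic) mean of a trait under Brownian motion,
#' `a = (1' C^-1 1)^-1 1' C^-1 x`, where `C` is the tree's BM covariance.
#' On a star tree this reduces to the arithmetic mean.
#'
#' @param x trait vector, named by tip or aligned with `C`.
#' @param C BM covariance matrix from [phylo_vcv()].
#' @param pseudo use a pseudo-inverse if `C` is singular (default off).
#' @return The scalar GLS mean.
#' @export
gls_mean <- function(x, C, pseudo = FALSE) {
  x <- align_trait(x, C)
  g <- gls_prep(C, pseudo = pseudo)
  sum(g$w * x) / g$s
}

#' Blomberg's K phylogenetic signal statistic
#'
#' K compares the observed mean squared error of tip data around the GLS
#' mean with the error expected under Brownian motion on the tree:
#' `K = (MSE0 / MSE) / E[MSE0 / MSE]`, where `MSE0 = d'd / (n - 1)`,
#' `MSE = d' C^-1 d / (n - 1)` with `d = x - a 1`, and the BM expectation of
#' the ratio is `(tr C - n / (1' C^-1 1)) / (n - 1)`. K is 1 when trait
#' variation accords perfectly with BM on the tree, near 0 for data random
#' with respect to the tree, and above 1 when values are more clumped within
#' clades than BM predicts. K is invariant to affine transformation of `x`.
#'
#' @inheritParams gls_mean
#' @return The scalar K (non-negative).
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' blomberg_k(c(A = 1, B = 2, C = 4), phylo_vcv(tr))
#' @export
blomberg_k <- function(x, C, pseudo = FALSE) {
  x <- align_trait(x, C)
  g <- gls_prep(C, pseudo = pseudo)
  if (g$n < 3L) stop("need at least 3 tips for K", call. = FALSE)
  d <- x - sum(g$w * x) / g$s
  if (all(abs(d) < .Machine$double.eps^0.5 * max(1, abs(x))))
    stop("zero variance: trait is constant across tips", call. = FALSE)
  mse0 <- sum(d^2)
  mse <- drop(crossprod(d, g$Cinv %*% d))
  expected_ratio <- (g$trC - g$n / g$s) / (g$n - 1)
  (mse0 / mse) / expected_ratio
}

#' Tip-randomization test of phylogenetic signal
#'
#' Permutes trait values across the tips of the tree and compares the GLS
#' mean squared error (lower = variation fits the tree better) of the
#' observed data with the permutation distribution. The p value uses the
#' add-one convention `p = (1 + #\{MSE_perm <= MSE_obs\}) / (n_perm + 1)`,
#' so ties count against the observed data and `p` is never 0; with the
#' default 999 permutations the smallest attainable p is 0.001.
#'
#' @inheritParams gls_mean
#' @param n_perm number of tip permutations.
#' @param seed optional integer seed for reproducible permutations.
#' @return List with `p`, `mse_obs`, `n_perm`.
#' @export
signal_test <- function(x, C, n_perm = 999L, seed = NULL, pseudo = FALSE) {
  x <- align_trait(x, C)
  g <- gls_prep(C, pseudo = pseudo)
  n <- g$n
  # MSE(x) = x' A x / (n - 1) with A the GLS residual-maker quadratic form;
  # the (n - 1) cancels in all comparisons and is dropped.
  A <- g$Cinv - tcrossprod(g$w) / g$s
  mse_obs <- drop(crossprod(x, A %*% x))
  idx <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
  })
  Xp <- matrix(x[idx], nrow = n)
  mse_perm <- colSums(Xp * (A %*% Xp))
  tol <- 1e-12 * max(1, abs(mse_obs))
  p <- (1 + sum(mse_perm <= mse_obs + tol)) / (n_perm + 1)
  list(p = p, mse_obs = mse_obs / (n - 1), n_perm = as.integer(n_perm))
}

#' Phylogenetic signal of a trait over a tree sample
#'
#' Runs the two-step signal procedure on every tree of a sample: first the
#' tip-randomization test against the null that the data are random with
#' respect to the tree, then Blomberg's K to measure the strength of signal.
#' Results are aggregated as the mean and standard deviation of K and the
#' maximum p across trees. Per-tree permutation seeds are derived
#' deterministically from `seed`, so results do not depend on iteration
#' order.
#'
#' @param trait name of the trait column.
#' @param table trait table: `data.frame` with `language_id` plus trait
#'   columns (see [functional_load_table()]).
#' @param trees a `multiPhylo` sample (see [read_tree_sample()]); each tree
#'   is pruned to the table's languages.
#' @param n_perm permutations per tree.
#' @param seed integer seed for the whole run.
#' @param pseudo passed to the GLS routines.
#' @return Object of class `"k_result"`: list with `trait`, per-tree `K` and
#'   `p` vectors, `mean_K`, `sd_K`, `max_p`, `n_perm`, `seed`.
#' @export
signal_over_sample <- function(trait, table, trees, n_perm = 999L,
                               seed = NULL, pseudo = FALSE) {
  trees <- as_tree_sample(trees)
  if (!trait %in% names(table))
    stop("trait '", trait, "' not in table", call. = FALSE)
  x <- stats::setNames(table[[trait]], table$language_id)
  if (anyNA(x)) stop("trait '", trait, "' has missing values", call. = FALSE)
  seeds <- derive_seeds(seed, length(trees))
  K <- p <- numeric(length(trees))
  for (i in seq_along(trees)) {
    tr <- prune_tree(trees[[i]], names(x))
    C <- phylo_vcv(tr)
    K[i] <- blomberg_k(x, C, pseudo = pseudo)
    p[i] <- signal_test(x, C, n_perm = n_perm, seed = seeds[[i]],
                        pseudo = pseudo)$p
  }
  structure(
    list(trait = trait, K = K, p = p,
         mean_K = mean(K), sd_K = stats::sd(K), max_p = max(p),
         n_perm = as.integer(n_perm), seed = seed),
    class = "k_result"
  )
}

#' @export
print.k_result <- function(x, ...) {
  cat(sprintf(
    "Phylogenetic signal in %s over %d tree(s): mean K = %.3f (sd %.3f), max p = %.3g [%d permutations]\n",
    x$trait, length(x$K), x$mean_K,
    if (length(x$K) > 1L) x$sd_K else NA_real_, x$max_p, x$n_perm))
  invisible(x)
}

#' @export
as.data.frame.k_result <- function(x, ...) {
  data.frame(trait = x$trait, tree_index = seq_along(x$K), K = x$K, p = x$p,
             stringsAsFactors = FALSE)
}
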
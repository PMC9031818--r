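# Independent oracles and fixtures shared across the suite. These are
# deliberately written from first principles (direct summation, explicit
# matrix algebra, Felsenstein's pruning recursion) so they do not share code
# with the implementation they check.

# --- fixtures -------------------------------------------------------------

toy_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

toy_segment_table <- function() {
  segment_table(
    symbol = c("a", "a:", "i", "i:", "u", "u:", "p", "t", "d", "r", "n",
               "nt", "w", "j"),
    class = c(rep("vowel", 6), rep("consonant", 8)),
    length = c("short", "long", "short", "long", "short", "long",
               rep(NA, 8)),
    length_partner = c("a:", "a", "i:", "i", "u:", "u", rep(NA, 8)),
    place = c(rep(NA, 6), "labial", "apical", "apical", "apical", "apical",
              "apical", "labial", "palatal"),
    manner = c(rep(NA, 6), "stop", "stop", "voiced", "rhotic", "nasal",
               "prestopped", "glide", "glide")
  )
}

profile_from_counts <- function(vowel, consonant, count, id = "toy") {
  flphylo:::new_domain_profile(
    id,
    data.frame(vowel = vowel, consonant = consonant, count = as.integer(count),
               stringsAsFactors = FALSE)
  )
}

# four equiprobable types crossing a length and a voicing distinction
toy_profile_4 <- function() {
  profile_from_counts(c("a", "a:", "a", "a:"), c("t", "t", "d", "d"),
                      c(1, 1, 1, 1))
}

# --- entropy / FL oracles -------------------------------------------------

# direct summation over an explicit probability table
entropy_oracle <- function(counts) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# binary entropy and the closed-form FL of the theta-mixture generator
h2 <- function(p) {
  ifelse(p <= 0 | p >= 1, 0, -p * log2(p) - (1 - p) * log2(1 - p))
}
flv_closed <- function(theta) 1 + h2(theta) / 2 - h2(theta / 2)
flc_closed <- function(theta) 1 + h2(theta) / 2 - h2((1 - theta) / 2)
mixture_entropy_closed <- function(theta) 1 + h2(theta) / 2

# --- GLS / PIC oracles ----------------------------------------------------

# explicit matrix arithmetic, no shared code with gls_prep()
gls_mean_oracle <- function(x, C) {
  Ci <- solve(C)
  ones <- rep(1, length(x))
  drop(t(ones) %*% Ci %*% x) / drop(t(ones) %*% Ci %*% ones)
}

blomberg_k_oracle <- function(x, C) {
  n <- length(x)
  Ci <- solve(C)
  a <- gls_mean_oracle(x, C)
  d <- x - a
  mse0 <- sum(d^2) / (n - 1)
  mse <- drop(t(d) %*% Ci %*% d) / (n - 1)
  denom <- (sum(diag(C)) - n / sum(Ci)) / (n - 1)
  (mse0 / mse) / denom
}

# Felsenstein pruning: returns the REML root estimate and the standardized
# independent contrasts of a trait on a rooted tree.
pic_oracle <- function(x, tree) {
  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  val <- c(x[tree$tip.label], rep(NA_real_, tree$Nnode))
  extra <- numeric(ntip + tree$Nnode)  # branch-length inflation
  el <- tree$edge.length
  contrasts <- numeric(0)
  # bottom-up: repeatedly resolve parents whose children both have values
  edges <- tree$edge
  done <- rep(FALSE, nrow(edges))
  repeat {
    ready <- which(!done &
                     !is.na(val[edges[, 2L]]))
    if (length(ready) == 0L) break
    # group ready edges by parent; resolve parents whose all children ready
    for (parent in unique(edges[ready, 1L])) {
      ce <- which(edges[, 1L] == parent)
      if (any(is.na(val[edges[ce, 2L]]))) next
      stopifnot(length(ce) == 2L)  # binary trees only in this oracle
      i <- edges[ce[1L], 2L]; j <- edges[ce[2L], 2L]
      vi <- el[ce[1L]] + extra[i]; vj <- el[ce[2L]] + extra[j]
      contrasts <- c(contrasts, (val[i] - val[j]) / sqrt(vi + vj))
      val[parent] <- (vj * val[i] + vi * val[j]) / (vi + vj)
      extra[parent] <- vi * vj / (vi + vj)
      done[ce] <- TRUE
    }
    if (all(done)) break
  }
  list(root = unname(val[ntip + 1L]), contrasts = contrasts)
}

expect_no_failure <- function(expr) expect_silent(invisible(expr))
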
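#' Simulate a dated pure-birth (Yule) tree
#'
#' Generates an ultrametric tree conditioned on the number of tips, with tip
#' labels `L1 ... Ln`. Serves as a stand-in for a dated language phylogeny
#' when exercising the pipeline.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate speciation rate per unit time.
#' @param seed optional integer seed; the same seed yields the same tree.
#' @return A rooted ultrametric `phylo`.
#' @export
yule_tree <- function(n_tips, birth_rate = 1, seed = NULL) {
  if (n_tips < 2L) stop("need at least 2 tips", call. = FALSE)
  tree <- with_seed(seed, ape::rphylo(n_tips, birth = birth_rate, death = 0))
  tree$tip.label <- paste0("L", seq_len(n_tips))
  tree
}

#' Simulate Brownian-motion trait evolution on a tree
#'
#' Draws independent Gaussian increments on each branch (variance = rate x
#' branch length) and accumulates them from the root, so tip values are
#' multivariate normal with covariance `R` (the rate matrix) Kronecker the
#' tree's BM covariance `C`. A scalar `rate` gives one trait; a `k x k`
#' symmetric positive semi-definite rate matrix gives `k` correlated traits
#' whose per-branch increments have cross-covariance `R * branch length`.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param rate scalar rate or symmetric PSD rate matrix `R`.
#' @param root root state(s); recycled to the number of traits.
#' @param seed optional integer seed.
#' @param trait_names column names for the traits.
#' @return A `data.frame` with `language_id` and one column per trait.
#' @examples
#' tr <- yule_tree(8, seed = 1)
#' simulate_bm(tr, rate = matrix(c(1, -0.5, -0.5, 1), 2), seed = 2)
#' @export
simulate_bm <- function(tree, rate = 1, root = 0, seed = NULL,
                        trait_names = NULL) {
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  R <- if (is.matrix(rate)) rate else matrix(rate, 1L, 1L)
  if (!isSymmetric(unname(R)))
    stop("rate matrix must be symmetric", call. = FALSE)
  eg <- eigen(R, symmetric = TRUE)
  if (min(eg$values) < -1e-10 * max(abs(eg$values), 1))
    stop("rate matrix must be positive semi-definite", call. = FALSE)
  # matrix square root; tolerates the singular (|rho| = 1) boundary
  Rhalf <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
  k <- nrow(R)
  tree <- stats::reorder(tree, "cladewise")  # parents precede children
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  vals <- matrix(NA_real_, nnode, k)
  root_node <- ntip + 1L
  vals[root_node, ] <- rep_len(root, k)
  z <- with_seed(seed, matrix(rnorm(nrow(tree$edge) * k), ncol = k))
  inc <- (z %*% Rhalf) * sqrt(tree$edge.length)
  for (e in seq_len(nrow(tree$edge))) {
    vals[tree$edge[e, 2L], ] <- vals[tree$edge[e, 1L], ] + inc[e, ]
  }
  tips <- vals[seq_len(ntip), , drop = FALSE]
  colnames(tips) <- trait_names %||% paste0("trait", seq_len(k))
  data.frame(language_id = tree$tip.label, tips, stringsAsFactors = FALSE)
}

#' Default synthetic segment inventory
#'
#' A minimal inventory sufficient for every contrast the pipeline studies:
#' the length pair a/a:, an initial consonant `p`, and voiceless/voiced
#' stops at one or two places of articulation (`t`/`d`, optionally `k`/`g`).
#' With two places, consonant place varies independently of the
#' length/manner trade-off, providing a trait (`FLP`) expected to be
#' uncorrelated with `FLV`.
#'
#' @param two_places include the velar pair `k`/`g`.
#' @return A [segment_table()].
#' @export
synth_segment_table <- function(two_places = FALSE) {
  sym <- c("a", "a:", "p", "t", "d")
  cls <- c("vowel", "vowel", "consonant", "consonant", "consonant")
  len <- c("short", "long", NA, NA, NA)
  par <- c("a:", "a", NA, NA, NA)
  plc <- c(NA, NA, "labial", "apical", "apical")
  man <- c(NA, NA, "stop", "stop", "voiced")
  if (two_places) {
    sym <- c(sym, "k", "g")
    cls <- c(cls, "consonant", "consonant")
    len <- c(len, NA, NA)
    par <- c(par, NA, NA)
    plc <- c(plc, "velar", "velar")
    man <- c(man, "stop", "voiced")
  }
  segment_table(sym, cls, len, par, plc, man)
}

#' Generate a synthetic lexicon with a length/manner trade-off
#'
#' Emits `n_words` CVCV wordforms (`p V C a`, space-delimited) whose domain
#' distribution is a theta-mixture of two sources of distinctiveness: with
#' probability `1 - theta` the instance draws its contrast from vowel length
#' (short/long equiprobable, manner fixed to the voiceless stop), and with
#' probability `theta` from consonant manner (stop/voiced equiprobable,
#' vowel short). In expectation the vowel-length FL falls from 1 bit at
#' `theta = 0` to 0 at `theta = 1` while the manner FL rises from 0 to
#' 1 bit, emulating a diachronic flow of contrastiveness from the tonic
#' vowel to the following consonant. Consonant place is drawn independently
#' of `theta` from `place_probs`.
#'
#' @param theta trade-off parameter in `[0, 1]`.
#' @param n_words number of wordforms.
#' @param language_id identifier written into the lexicon.
#' @param table inventory; needs a short/long vowel pair and two manners at
#'   one place (see [synth_segment_table()]).
#' @param place_probs named probabilities over place labels for the
#'   post-tonic consonant (default: the single apical place).
#' @param seed optional integer seed.
#' @return A `data.frame` with `language_id` and space-delimited `form`,
#'   readable by [domain_profile()] with `segmented = TRUE`.
#' @export
synth_lexicon <- function(theta, n_words, language_id = "synth",
                          table = synth_segment_table(),
                          place_probs = c(apical = 1), seed = NULL) {
  stopifnot(theta >= 0, theta <= 1, n_words >= 1L)
  cons <- table[table$class == "consonant", ]
  short <- table$symbol[table$class == "vowel" & !is.na(table$length) &
                          table$length == "short" &
                          !is.na(table$length_partner)][1L]
  if (is.na(short))
    stop("inventory lacks a short/long vowel pair", call. = FALSE)
  long <- table$length_partner[match(short, table$symbol)]
  cons_sym <- function(place, manner) {
    s <- cons$symbol[cons$place == place & cons$manner == manner]
    if (length(s) == 0L)
      stop("inventory lacks a '", manner, "' consonant at place '", place,
           "'", call. = FALSE)
    s[1L]
  }
  places <- names(place_probs)
  grid <- expand.grid(place = places, manner = c("stop", "voiced"),
                      stringsAsFactors = FALSE)
  lookup <- stats::setNames(
    mapply(cons_sym, grid$place, grid$manner, USE.NAMES = FALSE),
    paste(grid$place, grid$manner)
  )
  with_seed(seed, {
    use_manner <- runif(n_words) < theta
    place <- places[sample.int(length(places), n_words, replace = TRUE,
                               prob = place_probs)]
    coin <- runif(n_words) < 0.5
    vowel <- ifelse(use_manner, short, ifelse(coin, short, long))
    manner <- ifelse(use_manner & coin, "voiced", "stop")
    consonant <- unname(lookup[paste(place, manner)])
    data.frame(
      language_id = language_id,
      form = paste("p", vowel, consonant, "a"),
      stringsAsFactors = FALSE
    )
  })
}

#' Evolve a family of lexicons with a heritable trade-off
#'
#' End-to-end test harness for the comparative pipeline: a latent trait
#' evolves by univariate Brownian motion on the tree, is mapped through a
#' logistic function to a per-language trade-off parameter `theta`, and each
#' tip's lexicon is generated with [synth_lexicon()] at its `theta`. A
#' second, independent latent trait evolves the place-of-articulation
#' proportion the same way, so that every FL variable is tree-structured
#' (as in real language families) while place remains independent of the
#' length/manner trade-off. Run through the pipeline, such data should show
#' phylogenetic signal in the vowel-length and consonant-manner FL, a
#' negative FLV-FLC correlation, and no FLV-FLP correlation.
#'
#' @param tree rooted `phylo` with branch lengths; tips become languages.
#' @param rate BM rate of the latent traits.
#' @param center,scale logistic mapping `theta = plogis((z - center)/scale)`;
#'   BM runs on the unconstrained latent scale, avoiding boundary
#'   reflection.
#' @param n_words_range lexicon sizes are drawn uniformly from this range
#'   (default 208-3215, the span typical of comparative wordlists).
#' @param two_places use the two-place inventory so `FLP` is defined; the
#'   apical/velar proportion then follows the second latent trait.
#' @param seed integer seed for the whole generation.
#' @return List with `lexicons` (stacked `data.frame`), `table` (the
#'   [segment_table()]), `theta`, `latent`, `place_prop` (named per-tip
#'   vectors), and `n_words`.
#' @export
evolve_tradeoff <- function(tree, rate = 1, center = 0, scale = 1,
                            n_words_range = c(208L, 3215L),
                            two_places = TRUE, seed = NULL) {
  seeds <- derive_seeds(seed, 3L + length(tree$tip.label))
  bm <- simulate_bm(tree, rate = rate, root = center, seed = seeds[[1L]],
                    trait_names = "latent")
  latent <- stats::setNames(bm$latent, bm$language_id)
  theta <- stats::plogis((latent - center) / scale)
  tab <- synth_segment_table(two_places = two_places)
  place_prop <- if (two_places) {
    bm2 <- simulate_bm(tree, rate = rate, root = 0, seed = seeds[[2L]],
                       trait_names = "latent_place")
    stats::plogis(stats::setNames(bm2$latent_place, bm2$language_id) / scale)
  } else {
    stats::setNames(rep(1, length(theta)), names(theta))
  }
  n_words <- with_seed(seeds[[3L]], {
    sample(seq.int(n_words_range[1L], n_words_range[2L]),
           length(theta), replace = TRUE)
  })
  lex <- vector("list", length(theta))
  for (i in seq_along(theta)) {
    probs <- if (two_places)
      c(apical = place_prop[[i]], velar = 1 - place_prop[[i]])
    else c(apical = 1)
    lex[[i]] <- synth_lexicon(theta[i], n_words[i],
                              language_id = names(theta)[i], table = tab,
                              place_probs = probs,
                              seed = seeds[[3L + i]])
  }
  list(lexicons = do.call(rbind, lex), table = tab, theta = theta,
       latent = latent, place_prop = place_prop,
       n_words = stats::setNames(n_words, names(theta)))
}
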
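#' Shannon entropy of a domain profile
#'
#' Entropy in bits of the distribution of vowel-consonant string types,
#' `H = -sum Pr(s) log2 Pr(s)`, with `Pr(s)` the type-count proportion.
#' Empty and single-type profiles have `H = 0`.
#'
#' @param profile a [domain_profile()].
#' @return Entropy in bits.
#' @export
profile_entropy <- function(profile) {
  n <- profile$n_instances
  if (n == 0L || nrow(profile$types) < 2L) return(0)
  p <- profile$types$count / n
  -sum(p * log2(p))
}

#' Specify a phonological contrast
#'
#' A contrast is a collection of pairwise-disjoint sets of segment symbols,
#' acting on one slot of the vowel-consonant string. Collapsing the contrast
#' rewrites all members of each set to one fresh placeholder symbol, thereby
#' removing the distinctions *within* each set while preserving all others.
#'
#' @param name short label, e.g. `"FLV"`.
#' @param sets list of character vectors; each set needs at least two
#'   members, and sets must be pairwise disjoint. An empty list is allowed
#'   and yields a vacuous contrast (functional load 0).
#' @param slot `"vowel"` or `"consonant"`: which component the sets act on.
#' @return An object of class `"contrast_spec"`.
#' @export
contrast_spec <- function(name, sets, slot = c("vowel", "consonant")) {
  slot <- match.arg(slot)
  sets <- lapply(sets, as.character)
  if (any(vapply(sets, length, 1L) < 2L))
    stop("every contrast set needs at least 2 members", call. = FALSE)
  all_members <- unlist(sets)
  if (anyDuplicated(all_members))
    stop("contrast sets overlap: ",
         paste(unique(all_members[duplicated(all_members)]), collapse = ", "),
         call. = FALSE)
  structure(list(name = name, sets = sets, slot = slot),
            class = "contrast_spec")
}

#' @export
print.contrast_spec <- function(x, ...) {
  cat("Contrast '", x$name, "' (slot: ", x$slot, "): ",
      paste(vapply(x$sets, function(s) paste0("{", paste(s, collapse = ","), "}"),
                   ""), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Collapse a contrast in a domain profile
#'
#' Rewrites, in the contrast's slot only, each member of each contrast set to
#' a per-set placeholder distinct from every other symbol, then sums the
#' counts of string types made identical. The total instance count is
#' unchanged; by the grouping property of entropy the collapsed profile never
#' has higher entropy than the original.
#'
#' @param profile a [domain_profile()].
#' @param contrast a [contrast_spec()].
#' @return A new [domain_profile()].
#' @export
collapse_profile <- function(profile, contrast) {
  types <- profile$types
  if (nrow(types) == 0L || length(contrast$sets) == 0L) return(profile)
  col <- if (contrast$slot == "vowel") types$vowel else types$consonant
  for (k in seq_along(contrast$sets)) {
    col[col %in% contrast$sets[[k]]] <-
      sprintf("<%s.%d>", contrast$name, k)
  }
  if (contrast$slot == "vowel") types$vowel <- col else types$consonant <- col
  key <- paste(types$vowel, types$consonant, sep = "\t")
  agg <- rowsum(types$count, key)
  vc <- strsplit(rownames(agg), "\t", fixed = TRUE)
  out <- data.frame(
    vowel = vapply(vc, `[[`, "", 1L),
    consonant = vapply(vc, `[[`, "", 2L),
    count = as.integer(agg[, 1L]),
    stringsAsFactors = FALSE
  )
  new_domain_profile(profile$language_id, out, n_words = profile$n_words)
}

#' Functional load of a contrast
#'
#' The functional load (FL) of a contrast is the entropy difference between
#' the original domain profile and the profile with the contrast collapsed:
#' `fl = H - H_collapsed` (bits). The normalized variant expresses this
#' relative to the domain's entropy, `fl_norm = fl / H`, in `[0, 1]`. When
#' `H = 0` the normalized load is defined as 0 (with a warning): a domain
#' with no distinctions has no load to apportion.
#'
#' @param profile a [domain_profile()].
#' @param contrast a [contrast_spec()].
#' @return An object of class `"fl_result"`: list with `language_id`,
#'   `contrast`, `H`, `H_collapsed`, `fl`, `fl_norm`.
#' @examples
#' tab <- synth_segment_table()
#' prof <- domain_profile(c("p a t a", "p a: t a", "p a d a", "p a: d a"),
#'                        tab, "toy")
#' functional_load(prof, build_contrasts(tab)$FLV)
#' @export
functional_load <- function(profile, contrast) {
  H <- profile_entropy(profile)
  Hc <- profile_entropy(collapse_profile(profile, contrast))
  fl <- H - Hc
  # merging categories cannot increase entropy; zap negative rounding noise
  if (fl < 0) {
    stopifnot(fl > -1e-9)
    fl <- 0
  }
  if (H > 0) {
    fl_norm <- fl / H
  } else {
    warning("profile entropy is 0; normalized functional load set to 0",
            call. = FALSE)
    fl_norm <- 0
  }
  structure(
    list(language_id = profile$language_id, contrast = contrast$name,
         H = H, H_collapsed = Hc, fl = fl, fl_norm = fl_norm),
    class = "fl_result"
  )
}

#' @export
print.fl_result <- function(x, ...) {
  cat(sprintf("FL[%s] %s: H = %.4f, H' = %.4f, fl = %.4f bits, fl_norm = %.4f\n",
              x$contrast, x$language_id, x$H, x$H_collapsed, x$fl, x$fl_norm))
  invisible(x)
}

#' Build the three canonical contrasts from a segment table
#'
#' Constructs the contrast specifications for tonic vowel length (`FLV`:
#' one set per partnered short/long vowel pair), post-tonic consonant manner
#' (`FLC`: consonants grouped by shared place, so that collapsing removes
#' manner distinctions), and post-tonic consonant place (`FLP`: consonants
#' grouped by shared manner). Singleton groups carry no distinction and are
#' dropped.
#'
#' @param table a [segment_table()].
#' @return Named list of [contrast_spec()]: `FLV`, `FLC`, `FLP`.
#' @export
build_contrasts <- function(table) {
  vow <- table[table$class == "vowel" & !is.na(table$length_partner), ]
  pair_key <- apply(cbind(vow$symbol, vow$length_partner), 1L,
                    function(r) paste(sort(r), collapse = "\t"))
  flv_sets <- lapply(unique(pair_key),
                     function(k) strsplit(k, "\t", fixed = TRUE)[[1L]])
  cons <- table[table$class == "consonant", ]
  by_place <- split(cons$symbol, cons$place)
  by_manner <- split(cons$symbol, cons$manner)
  list(
    FLV = contrast_spec("FLV", flv_sets, slot = "vowel"),
    FLC = contrast_spec("FLC", Filter(function(s) length(s) >= 2L, by_place),
                        slot = "consonant"),
    FLP = contrast_spec("FLP", Filter(function(s) length(s) >= 2L, by_manner),
                        slot = "consonant")
  )
}

#' Per-language functional-load trait table
#'
#' Computes the six FL variables (unnormalized and normalized vowel-length,
#' consonant-manner, and consonant-place FL) for a set of domain profiles.
#'
#' @param profiles list of [domain_profile()] objects.
#' @param tables shared [segment_table()] or named list per language.
#' @return A `data.frame` with columns `language_id`, `FLVu`, `FLCu`,
#'   `FLPu`, `FLVn`, `FLCn`, `FLPn`.
#' @export
functional_load_table <- function(profiles, tables) {
  rows <- lapply(profiles, function(p) {
    tab <- table_for(tables, p$language_id)
    ctr <- build_contrasts(tab)
    v <- functional_load(p, ctr$FLV)
    cc <- functional_load(p, ctr$FLC)
    pp <- functional_load(p, ctr$FLP)
    data.frame(
      language_id = p$language_id,
      FLVu = v$fl, FLCu = cc$fl, FLPu = pp$fl,
      FLVn = v$fl_norm, FLCn = cc$fl_norm, FLPn = pp$fl_norm,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
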
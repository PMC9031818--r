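#' Read lexicons from a tab-separated wordlist file
#'
#' Each line holds `language_id<TAB>form`; lines starting with `#` are
#' ignored. Forms are either contiguous strings (to be tokenized against a
#' segment table) or already space-delimited segments.
#'
#' @param path path to a UTF-8 TSV file.
#' @return A `data.frame` with columns `language_id` and `form`.
#' @seealso [domain_profile()], [tokenize_form()]
#' @export
read_lexicons <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 2L
  if (any(bad))
    stop("malformed lexicon line(s) (need language_id<TAB>form): line ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  data.frame(
    language_id = trimws(vapply(parts, `[[`, "", 1L)),
    form = trimws(vapply(parts, `[[`, "", 2L)),
    stringsAsFactors = FALSE
  )
}

#' Tokenize a raw wordform into segment symbols
#'
#' Greedy longest-match tokenization, left to right, over the symbols of a
#' segment table. Multi-character symbols (digraphs, geminates, pre-stopped
#' sonorants) therefore come out as single segments. The concatenation of the
#' output always reproduces the input.
#'
#' @param raw_form a single string.
#' @param table a [segment_table()].
#' @return Character vector of segment symbols.
#' @examples
#' tab <- synth_segment_table()
#' tokenize_form("pata:ta", tab)
#' @export
tokenize_form <- function(raw_form, table) {
  stopifnot(is.character(raw_form), length(raw_form) == 1L)
  syms <- table$symbol[order(nchar(table$symbol), decreasing = TRUE)]
  out <- character(0)
  i <- 1L
  n <- nchar(raw_form)
  while (i <= n) {
    hit <- NA_character_
    for (s in syms) {
      if (substr(raw_form, i, i + nchar(s) - 1L) == s) {
        hit <- s
        break
      }
    }
    if (is.na(hit))
      stop("cannot tokenize '", raw_form, "' at position ", i,
           ": unmatched residue '", substr(raw_form, i, n), "'",
           call. = FALSE)
    out <- c(out, hit)
    i <- i + nchar(hit)
  }
  out
}

#' Normalize vowel length in a segment string
#'
#' Applies, in a single deterministic left-to-right pass, the length
#' conventions used when classifying tonic vowels as short or long:
#' two adjacent identical short vowels are rewritten as the long partner
#' (`a a` -> `a:`), and the high-vowel-glide sequences `u w u` and `i j i`
#' are rewritten as long `u` and long `i`. Triple matches are checked before
#' pair matches at each position; the pass never revisits its own output, so
#' the operation is idempotent.
#'
#' @param segments character vector of segment symbols (already tokenized).
#' @param table a [segment_table()].
#' @param glide_triples named character vector mapping a short high vowel to
#'   the homorganic glide that may spell its long counterpart.
#' @return Character vector of segment symbols.
#' @export
normalize_vowel_length <- function(segments, table,
                                   glide_triples = c(u = "w", i = "j")) {
  n <- length(segments)
  if (n < 2L) return(segments)
  # fast path: nothing to fuse
  if (!any(segments[-n] == segments[-1L]) &&
      !any(segments %in% glide_triples)) {
    return(segments)
  }
  cls <- seg_lookup(table, "class")
  len <- seg_lookup(table, "length")
  partner <- seg_lookup(table, "length_partner")
  out <- character(0)
  i <- 1L
  while (i <= n) {
    s <- segments[i]
    short_vowel <- !is.na(cls[s]) && cls[s] == "vowel" &&
      !is.na(len[s]) && len[s] == "short"
    if (short_vowel) {
      glide <- glide_triples[s]
      if (i + 2L <= n && !is.na(glide) && segments[i + 1L] == glide &&
          segments[i + 2L] == s) {
        out <- c(out, long_partner_of(s, partner, table))
        i <- i + 3L
        next
      }
      if (i + 1L <= n && segments[i + 1L] == s) {
        out <- c(out, long_partner_of(s, partner, table))
        i <- i + 2L
        next
      }
    }
    out <- c(out, s)
    i <- i + 1L
  }
  out
}

long_partner_of <- function(s, partner, table) {
  p <- partner[s]
  if (is.na(p))
    stop("short vowel '", s, "' has adjacent-identical (or glide) sequence ",
         "but no long partner in the segment table", call. = FALSE)
  unname(p)
}

#' Extract the tonic-vowel + post-tonic consonant domain from a word
#'
#' The domain of interest is the word's first (tonic) vowel followed by
#' exactly one intervocalic consonant. An instance is returned only when the
#' segment after the tonic vowel is a single consonant that is itself
#' followed by a vowel; clusters, vowel hiatus, and word-final consonants
#' yield no instance.
#'
#' @param segments normalized segment vector (see [normalize_vowel_length()]).
#' @param table a [segment_table()].
#' @return A list with elements `vowel`, `vowel_length`, `consonant`,
#'   `place`, `manner`, or `NULL` when the word contains no such domain.
#' @export
extract_domain <- function(segments, table) {
  cls <- seg_lookup(table, "class")[segments]
  if (anyNA(cls))
    stop("segment(s) not in table: ",
         paste(unique(segments[is.na(cls)]), collapse = ", "), call. = FALSE)
  i <- match("vowel", cls)
  if (is.na(i) || i + 2L > length(segments)) return(NULL)
  if (cls[i + 1L] != "consonant" || cls[i + 2L] != "vowel") return(NULL)
  v <- segments[i]
  c_ <- segments[i + 1L]
  row <- match(c_, table$symbol)
  list(
    vowel = v,
    vowel_length = table$length[match(v, table$symbol)],
    consonant = c_,
    place = table$place[row],
    manner = table$manner[row]
  )
}

#' Profile the domain distribution of a lexicon
#'
#' Tokenizes (if needed), normalizes vowel length, extracts at most one
#' domain instance per word (the tonic syllable is unique), and tabulates the
#' resulting vowel-consonant string types. Probabilities are type counts over
#' extracted instances: the input wordlists are lexical (type) lists, so no
#' token-frequency weighting is applied; duplicated wordforms each count.
#'
#' @param forms character vector of wordforms for one language.
#' @param table a [segment_table()].
#' @param language_id language identifier attached to the profile.
#' @param segmented if `TRUE`, forms are space-delimited segment strings;
#'   otherwise they are tokenized with [tokenize_form()].
#' @return An object of class `"domain_profile"`: a list with `language_id`,
#'   `types` (`data.frame` with `vowel`, `consonant`, `count`),
#'   `n_instances`, `n_words`.
#' @examples
#' tab <- synth_segment_table()
#' domain_profile(c("p a t a", "p a a t a", "p a d a"), tab, "toy")
#' @export
domain_profile <- function(forms, table, language_id = "", segmented = TRUE) {
  segs <- if (segmented) {
    strsplit(forms, " ", fixed = TRUE)
  } else {
    lapply(forms, tokenize_form, table = table)
  }
  keys <- character(length(segs))
  for (w in seq_along(segs)) {
    s <- segs[[w]]
    if (length(s) == 0L) next
    s <- normalize_vowel_length(s, table)
    inst <- extract_domain(s, table)
    if (!is.null(inst)) keys[w] <- paste(inst$vowel, inst$consonant, sep = "\t")
  }
  keys <- keys[nzchar(keys)]
  if (length(keys) == 0L) {
    types <- data.frame(vowel = character(0), consonant = character(0),
                        count = integer(0), stringsAsFactors = FALSE)
    return(new_domain_profile(language_id, types, n_words = length(forms)))
  }
  counts <- table(keys)
  vc <- strsplit(names(counts), "\t", fixed = TRUE)
  types <- data.frame(
    vowel = vapply(vc, `[[`, "", 1L),
    consonant = vapply(vc, `[[`, "", 2L),
    count = as.integer(counts),
    stringsAsFactors = FALSE
  )
  new_domain_profile(language_id, types, n_words = length(forms))
}

new_domain_profile <- function(language_id, types, n_words = NA_integer_) {
  structure(
    list(
      language_id = language_id,
      types = types,
      n_instances = sum(types$count),
      n_words = n_words
    ),
    class = "domain_profile"
  )
}

#' @export
print.domain_profile <- function(x, ...) {
  cat("Domain profile for '", x$language_id, "': ", nrow(x$types),
      " string types over ", x$n_instances, " instances\n", sep = "")
  invisible(x)
}

#' Apply the language inclusion filters
#'
#' A language enters the comparative analyses only if its profile has
#' strictly more than `min_instances` domain instances and at least one
#' short/long vowel pair has both members attested among its tonic vowels
#' (i.e. the language retains some degree of tonic vowel length contrast).
#'
#' @param profiles list of [domain_profile()] objects.
#' @param tables a single [segment_table()] shared by all languages, or a
#'   named list mapping `language_id` to its table.
#' @param min_instances inclusion threshold; languages with
#'   `n_instances > min_instances` are kept.
#' @return Character vector of retained `language_id`s.
#' @export
filter_languages <- function(profiles, tables, min_instances = 200L) {
  keep <- vapply(profiles, function(p) {
    tab <- table_for(tables, p$language_id)
    is.na(language_exclusion_reason(p, tab, min_instances))
  }, logical(1L))
  vapply(profiles[keep], `[[`, "", "language_id")
}

# NA = passes; otherwise a human-readable reason used in exclusion logs.
language_exclusion_reason <- function(profile, table, min_instances = 200L) {
  if (profile$n_instances <= min_instances)
    return(sprintf("only %d domain instances (need > %d)",
                   profile$n_instances, min_instances))
  vowels <- unique(profile$types$vowel)
  partner <- seg_lookup(table, "length_partner")
  attested_pair <- any(vowels %in% names(partner)[!is.na(partner)] &
                         partner[vowels] %in% vowels, na.rm = TRUE)
  if (!attested_pair)
    return("no short/long vowel pair with both members attested tonic")
  NA_character_
}

table_for <- function(tables, language_id) {
  if (inherits(tables, "segment_table")) return(tables)
  tab <- tables[[language_id]]
  if (is.null(tab))
    stop("no segment table for language '", language_id, "'", call. = FALSE)
  tab
}

#' Export domain profiles to CSV
#'
#' Writes the long-format table `language_id,vowel,consonant,count`.
#'
#' @param profiles list of [domain_profile()] objects.
#' @param path output CSV path.
#' @export
write_profiles <- function(profiles, path) {
  rows <- do.call(rbind, lapply(profiles, function(p) {
    if (nrow(p$types) == 0L) return(NULL)
    cbind(language_id = p$language_id, p$types)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
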
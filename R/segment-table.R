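#' Segment feature tables
#'
#' A segment table maps every segment symbol of a language to the features the
#' pipeline needs: major class (vowel/consonant), phonemic length and the
#' partner symbol of a short/long vowel pair, and place and manner of
#' articulation for consonants. Symbols may be multi-character (digraphs,
#' geminates, pre-stopped sonorants written as one unit), which the greedy
#' tokenizer then treats as single segments.
#'
#' @param symbol character vector of unique segment symbols.
#' @param class `"vowel"` or `"consonant"` for each symbol.
#' @param length `"short"`, `"long"`, or `NA` (consonants and lengthless
#'   vowels).
#' @param length_partner for each member of a short/long vowel pair, the
#'   symbol of the other member; `NA` otherwise.
#' @param place,manner categorical articulation labels; required for every
#'   consonant, `NA` for vowels.
#' @return A `data.frame` of class `"segment_table"` with one row per symbol.
#' @examples
#' segment_table(
#'   symbol = c("a", "a:", "t", "n"),
#'   class = c("vowel", "vowel", "consonant", "consonant"),
#'   length = c("short", "long", NA, NA),
#'   length_partner = c("a:", "a", NA, NA),
#'   place = c(NA, NA, "apical", "apical"),
#'   manner = c(NA, NA, "stop", "nasal")
#' )
#' @export
segment_table <- function(symbol, class, length = NA, length_partner = NA,
                          place = NA, manner = NA) {
  tab <- data.frame(
    symbol = as.character(symbol),
    class = as.character(class),
    length = as.character(rep_len(length, length(symbol))),
    length_partner = as.character(rep_len(length_partner, length(symbol))),
    place = as.character(rep_len(place, length(symbol))),
    manner = as.character(rep_len(manner, length(symbol))),
    stringsAsFactors = FALSE
  )
  class(tab) <- c("segment_table", "data.frame")
  validate_segment_table(tab)
  tab
}

#' Read a segment table from CSV
#'
#' Expects UTF-8 CSV with columns
#' `symbol,class,length,length_partner,place,manner`; empty cells are read as
#' `NA`.
#'
#' @param path path to the CSV file.
#' @return A [segment_table()].
#' @export
read_segment_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = c("", "NA"))
  need <- c("symbol", "class", "length", "length_partner", "place", "manner")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0L)
    stop("segment table '", path, "' lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  segment_table(raw$symbol, raw$class, raw$length, raw$length_partner,
                raw$place, raw$manner)
}

validate_segment_table <- function(tab) {
  if (nrow(tab) == 0L) stop("segment table is empty", call. = FALSE)
  if (anyDuplicated(tab$symbol))
    stop("duplicated segment symbol(s): ",
         paste(unique(tab$symbol[duplicated(tab$symbol)]), collapse = ", "),
         call. = FALSE)
  bad_class <- !tab$class %in% c("vowel", "consonant")
  if (any(bad_class))
    stop("segment class must be 'vowel' or 'consonant' (offending: ",
         paste(tab$symbol[bad_class], collapse = ", "), ")", call. = FALSE)
  cons <- tab[tab$class == "consonant", ]
  if (any(is.na(cons$place)) || any(is.na(cons$manner)))
    stop("every consonant needs non-empty place and manner labels",
         call. = FALSE)
  # length partnership must be symmetric and cross short/long
  paired <- tab[!is.na(tab$length_partner), ]
  for (i in seq_len(nrow(paired))) {
    p <- paired$length_partner[i]
    j <- match(p, tab$symbol)
    if (is.na(j))
      stop("length partner '", p, "' of '", paired$symbol[i],
           "' is not in the table", call. = FALSE)
    if (!identical(tab$length_partner[j], paired$symbol[i]))
      stop("length partnership not symmetric for '", paired$symbol[i], "'",
           call. = FALSE)
    if (identical(paired$length[i], tab$length[j]) ||
        any(is.na(c(paired$length[i], tab$length[j]))))
      stop("length partners must pair one short with one long vowel ('",
           paired$symbol[i], "')", call. = FALSE)
  }
  invisible(tab)
}

# fast lookups used in the hot profiling path
seg_lookup <- function(tab, field) {
  stats::setNames(tab[[field]], tab$symbol)
}
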
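test_that("greedy longest-match tokenization handles digraphs and round-trips", {
  tab <- toy_segment_table()
  expect_identical(tokenize_form("pata", tab), c("p", "a", "t", "a"))
  # 'nt' is a single (pre-stopped-style) symbol and must win over 'n'+'t'
  expect_identical(tokenize_form("panta", tab), c("p", "a", "nt", "a"))
  expect_error(tokenize_form("pax", tab), "residue 'x'")
  # round-trip property over random concatenations of symbols
  set.seed(42)
  for (i in 1:25) {
    segs <- sample(tab$symbol, sample(1:8, 1), replace = TRUE)
    toks <- tokenize_form(paste(segs, collapse = ""), tab)
    expect_identical(paste(toks, collapse = ""), paste(segs, collapse = ""))
  }
})

test_that("vowel-length normalization fuses VV and glide triples, idempotently", {
  tab <- toy_segment_table()
  expect_identical(normalize_vowel_length(c("p", "a", "a", "t", "a"), tab),
                   c("p", "a:", "t", "a"))
  expect_identical(normalize_vowel_length(c("p", "u", "w", "u", "t", "a"), tab),
                   c("p", "u:", "t", "a"))
  expect_identical(normalize_vowel_length(c("p", "i", "j", "i", "t", "a"), tab),
                   c("p", "i:", "t", "a"))
  expect_identical(normalize_vowel_length(c("p", "a", "t", "a"), tab),
                   c("p", "a", "t", "a"))
  # non-identical adjacent vowels are left as hiatus
  expect_identical(normalize_vowel_length(c("p", "a", "i", "t", "a"), tab),
                   c("p", "a", "i", "t", "a"))
  # missing long partner is a configuration error
  tab2 <- segment_table(c("e", "t", "a"), c("vowel", "consonant", "vowel"),
                        length = c("short", NA, "short"),
                        place = c(NA, "apical", NA),
                        manner = c(NA, "stop", NA))
  expect_error(normalize_vowel_length(c("e", "e", "t"), tab2), "long partner")
  # idempotence property under random segment strings
  set.seed(7)
  for (i in 1:25) {
    segs <- sample(tab$symbol, sample(2:9, 1), replace = TRUE)
    once <- normalize_vowel_length(segs, tab)
    expect_identical(normalize_vowel_length(once, tab), once)
  }
})

test_that("domain extraction takes the tonic vowel + single intervocalic consonant", {
  tab <- toy_segment_table()
  inst <- extract_domain(c("p", "a", "t", "a"), tab)
  expect_identical(inst[c("vowel", "vowel_length", "consonant")],
                   list(vowel = "a", vowel_length = "short", consonant = "t"))
  expect_identical(inst$manner, "stop")
  # cluster after the tonic vowel: not a single consonant
  expect_null(extract_domain(c("p", "a", "r", "t", "a"), tab))
  # word-final consonant: not intervocalic
  expect_null(extract_domain(c("p", "a", "t"), tab))
  # vowel hiatus after tonic
  expect_null(extract_domain(c("p", "a", "i", "t", "a"), tab))
  # no vowel at all
  expect_null(extract_domain(c("p", "t"), tab))
  # vowel-initial words are allowed; tonic is simply the first vowel
  expect_identical(extract_domain(c("a", "t", "a"), tab)$consonant, "t")
  # extraction ignores material after the following vowel
  a <- extract_domain(c("p", "a", "t", "a"), tab)
  b <- extract_domain(c("p", "a", "t", "a", "r", "i", "n", "a"), tab)
  expect_identical(a, b)
})

test_that("profiles count one instance per word with multiset semantics", {
  tab <- toy_segment_table()
  pr <- domain_profile(c("pata", "paata", "pada"), tab, "x", segmented = FALSE)
  expect_s3_class(pr, "domain_profile")
  expect_identical(pr$n_instances, 3L)
  got <- pr$types[order(pr$types$vowel, pr$types$consonant), ]
  expect_identical(got$count, c(1L, 1L, 1L))
  expect_true(all(paste(got$vowel, got$consonant) %in%
                    c("a t", "a d", "a: t")))
  # monosyllabic CVC words yield nothing
  expect_identical(domain_profile(c("pat", "tan"), tab, "y",
                                  segmented = FALSE)$n_instances, 0L)
  # duplicates count separately
  dup <- domain_profile(rep("pata", 5), tab, "z", segmented = FALSE)
  expect_identical(dup$types$count, 5L)
  # never more instances than words
  set.seed(11)
  forms <- replicate(40, paste(sample(tab$symbol, sample(1:6, 1), TRUE),
                               collapse = " "))
  pr2 <- domain_profile(forms, tab, "w")
  expect_lte(pr2$n_instances, length(forms))
})

test_that("language filters require > 200 instances and an attested length contrast", {
  tab <- toy_segment_table()
  mk <- function(id, n_at, n_longat) {
    profile_from_counts(c("a", "a:"), c("t", "t"), c(n_at, n_longat), id)
  }
  at_threshold <- mk("thresh", 150, 50)       # exactly 200: excluded
  above <- mk("above", 150, 51)               # 201: included
  no_long <- profile_from_counts("a", "t", 5000, "nolong")
  kept <- filter_languages(list(at_threshold, above, no_long), tab)
  expect_identical(kept, "above")
  # reasons are reported for the pipeline's exclusion log
  expect_match(flphylo:::language_exclusion_reason(at_threshold, tab),
               "200")
  expect_match(flphylo:::language_exclusion_reason(no_long, tab),
               "vowel pair")
})

test_that("lexicon TSV reader parses ids, forms, and comments", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "lgA\tp a t a", "lgB\tpata", ""), path)
  lex <- read_lexicons(path)
  expect_identical(lex$language_id, c("lgA", "lgB"))
  expect_identical(lex$form, c("p a t a", "pata"))
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("no_tab_here", bad)
  expect_error(read_lexicons(bad), "malformed")
})

test_that("segment table validation enforces the invariants", {
  expect_error(
    segment_table(c("a", "a"), c("vowel", "vowel")),
    "duplicated"
  )
  expect_error(
    segment_table("t", "consonant"),
    "place and manner"
  )
  # asymmetric partnership
  expect_error(
    segment_table(c("a", "a:", "e"), rep("vowel", 3),
                  length = c("short", "long", "short"),
                  length_partner = c("a:", "e", NA)),
    "symmetric|short with one long"
  )
  # partners must differ in length
  expect_error(
    segment_table(c("a", "e"), c("vowel", "vowel"),
                  length = c("short", "short"),
                  length_partner = c("e", "a")),
    "short with one long"
  )
})
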
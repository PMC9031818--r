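test_that("entropy matches hand-computed and brute-force values", {
  expect_equal(profile_entropy(toy_profile_4()), 2.0)
  p31 <- profile_from_counts(c("a", "a:"), c("t", "t"), c(3, 1))
  expect_equal(profile_entropy(p31), 0.811278, tolerance = 1e-6)
  expect_identical(profile_entropy(profile_from_counts("a", "t", 7)), 0)
  empty <- profile_from_counts(character(0), character(0), integer(0))
  expect_identical(profile_entropy(empty), 0)
  # brute-force oracle on random profiles with <= 6 types
  set.seed(3)
  for (i in 1:30) {
    k <- sample(1:6, 1)
    counts <- sample(1:50, k, replace = TRUE)
    pr <- profile_from_counts(paste0("v", 1:k), rep("t", k), counts)
    expect_equal(profile_entropy(pr), entropy_oracle(counts),
                 tolerance = 1e-12)
  }
})

test_that("collapsing a contrast merges strings and preserves totals", {
  len <- contrast_spec("FLV", list(c("a", "a:")), "vowel")
  pr <- profile_from_counts(c("a", "a:"), c("t", "t"), c(1, 1))
  col <- collapse_profile(pr, len)
  expect_identical(nrow(col$types), 1L)
  expect_identical(col$types$count, 2L)
  expect_identical(col$n_instances, pr$n_instances)
  # a contrast not distinguishing the attested strings changes nothing
  pr2 <- profile_from_counts(c("a", "a"), c("t", "d"), c(1, 1))
  col2 <- collapse_profile(pr2, len)
  expect_identical(sort(col2$types$count), c(1L, 1L))
  # total collapse of both slots leaves a single type with zero entropy
  all_v <- contrast_spec("V", list(c("a", "a:")), "vowel")
  all_c <- contrast_spec("C", list(c("t", "d")), "consonant")
  tot <- collapse_profile(collapse_profile(toy_profile_4(), all_v), all_c)
  expect_identical(nrow(tot$types), 1L)
  expect_identical(profile_entropy(tot), 0)
  # overlapping sets are a specification error
  expect_error(contrast_spec("bad", list(c("a", "a:"), c("a:", "i")), "vowel"),
               "overlap")
})

test_that("functional load reproduces the worked examples", {
  len <- contrast_spec("FLV", list(c("a", "a:")), "vowel")
  r4 <- functional_load(toy_profile_4(), len)
  expect_equal(r4$H, 2.0)
  expect_equal(r4$H_collapsed, 1.0)
  expect_equal(r4$fl, 1.0)
  expect_equal(r4$fl_norm, 0.5)
  p31 <- profile_from_counts(c("a", "a:"), c("t", "t"), c(3, 1))
  r31 <- functional_load(p31, len)
  expect_equal(r31$fl, 0.811278, tolerance = 1e-6)
  expect_equal(r31$fl_norm, 1.0)
  # contrast whose sets have <= 1 attested member: collapse is injective
  only_short <- profile_from_counts(c("a", "a"), c("t", "d"), c(2, 3))
  expect_equal(functional_load(only_short, len)$fl, 0)
  # zero-entropy profile: fl_norm defined as 0, with a warning
  single <- profile_from_counts("a", "t", 4)
  expect_warning(r0 <- functional_load(single, len), "entropy is 0")
  expect_identical(r0$fl_norm, 0)
})

test_that("FL invariants: bounds, placeholder freedom, count scaling", {
  set.seed(19)
  vow <- c("a", "a:", "i", "i:")
  con <- c("t", "d", "n")
  len <- contrast_spec("FLV", list(c("a", "a:"), c("i", "i:")), "vowel")
  for (i in 1:25) {
    k <- sample(2:6, 1)
    types <- unique(data.frame(
      vowel = sample(vow, k, TRUE), consonant = sample(con, k, TRUE),
      stringsAsFactors = FALSE))
    counts <- sample(1:30, nrow(types), replace = TRUE)
    pr <- profile_from_counts(types$vowel, types$consonant, counts)
    r <- functional_load(pr, len)
    expect_gte(r$fl, 0)
    expect_lte(r$fl, r$H + 1e-12)
    expect_gte(r$fl_norm, 0)
    expect_lte(r$fl_norm, 1)
    # uniform count scaling leaves FL unchanged
    pr10 <- profile_from_counts(types$vowel, types$consonant, counts * 10L)
    expect_equal(functional_load(pr10, len)$fl, r$fl, tolerance = 1e-12)
    # brute-force check of the collapsed entropy via explicit aggregation
    key <- ifelse(types$vowel %in% c("a", "a:"), "A",
                  ifelse(types$vowel %in% c("i", "i:"), "I", types$vowel))
    agg <- tapply(counts, paste(key, types$consonant), sum)
    expect_equal(r$H_collapsed, entropy_oracle(as.numeric(agg)),
                 tolerance = 1e-12)
  }
  # entropy of the collapse is invariant to the placeholder naming
  pr <- toy_profile_4()
  a <- collapse_profile(pr, contrast_spec("X", list(c("a", "a:")), "vowel"))
  b <- collapse_profile(pr, contrast_spec("LONGNAME", list(c("a", "a:")),
                                          "vowel"))
  expect_equal(profile_entropy(a), profile_entropy(b))
})

test_that("canonical contrasts are built from table features", {
  tab <- toy_segment_table()
  ctr <- build_contrasts(tab)
  flv <- lapply(ctr$FLV$sets, sort)
  expect_setequal(vapply(flv, paste, "", collapse = ","),
                  c("a,a:", "i,i:", "u,u:"))
  # FLC groups by place (manner distinctions collapse); singletons dropped
  apicals <- sort(c("t", "d", "r", "n", "nt"))
  expect_true(any(vapply(ctr$FLC$sets,
                         function(s) identical(sort(s), apicals), TRUE)))
  expect_identical(ctr$FLC$slot, "consonant")
  # FLP groups by manner
  stops <- sort(c("p", "t"))
  glides <- sort(c("w", "j"))
  flp <- lapply(ctr$FLP$sets, sort)
  expect_true(any(vapply(flp, identical, TRUE, stops)))
  expect_true(any(vapply(flp, identical, TRUE, glides)))
  # degenerate inventory: one consonant, no vowel pairs -> empty contrasts
  tiny <- segment_table(c("a", "t"), c("vowel", "consonant"),
                        place = c(NA, "apical"), manner = c(NA, "stop"))
  ctr0 <- build_contrasts(tiny)
  expect_length(ctr0$FLC$sets, 0)
  expect_length(ctr0$FLP$sets, 0)
  pr <- profile_from_counts(c("a", "a"), c("t", "t"), c(1, 2))
  expect_equal(functional_load(pr, ctr0$FLC)$fl, 0)
})

test_that("trait tables carry the six FL variables per language", {
  tab <- synth_segment_table(two_places = TRUE)
  lex1 <- synth_lexicon(0.2, 400, "lg1", tab,
                        place_probs = c(apical = .5, velar = .5), seed = 1)
  lex2 <- synth_lexicon(0.8, 400, "lg2", tab,
                        place_probs = c(apical = .5, velar = .5), seed = 2)
  profs <- list(
    domain_profile(lex1$form, tab, "lg1"),
    domain_profile(lex2$form, tab, "lg2")
  )
  fl <- functional_load_table(profs, tab)
  expect_identical(names(fl),
                   c("language_id", "FLVu", "FLCu", "FLPu",
                     "FLVn", "FLCn", "FLPn"))
  expect_identical(fl$language_id, c("lg1", "lg2"))
  # theta moves load from vowel length to consonant manner
  expect_gt(fl$FLVu[1], fl$FLVu[2])
  expect_lt(fl$FLCu[1], fl$FLCu[2])
})
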
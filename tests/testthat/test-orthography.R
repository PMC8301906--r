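test_that("shallow orthographies are bijective, consistent and deterministic", {
  tab <- build_shallow_orthography(4, feature_len = 8, seed = 1)
  expect_equal(nrow(tab$graphemes), 4)
  expect_equal(nrow(tab$phonemes), 4)
  expect_equal(nrow(tab$rules), 4)
  expect_true(all(tab$rules$prob == 1))
  expect_false(anyDuplicated(tab$rules$phoneme) > 0)  # bijection
  expect_equal(consistency_index(tab), 1)

  tab2 <- build_shallow_orthography(4, feature_len = 8, seed = 1)
  expect_identical(tab, tab2)
  tab3 <- build_shallow_orthography(4, feature_len = 8, seed = 2)
  expect_false(identical(tab$features, tab3$features))
})

test_that("grapheme allocation fails cleanly when the letter space is exhausted", {
  expect_error(build_shallow_orthography(400, seed = 1), "exhausted")
})

test_that("deep orthographies have the requested number of ambiguous graphemes", {
  tab <- build_deep_orthography(10, 0.5, feature_len = 8, seed = 2)
  multi <- table(tab$rules$grapheme)
  expect_equal(sum(multi >= 2), 5)          # round(0.5 * 10)
  expect_lt(consistency_index(tab), 1)
  # at least one phoneme reachable from two graphemes
  expect_gt(max(table(tab$rules$phoneme)), 1)
  # depth 1 with two alternatives each: mean rules per grapheme = 2
  tab1 <- build_deep_orthography(10, 1, feature_len = 8, seed = 3)
  expect_equal(nrow(tab1$rules) / nrow(tab1$graphemes), 2)
  expect_error(build_deep_orthography(10, 0), "shallow")
})

test_that("consistency index matches hand arithmetic and is order-invariant", {
  tab <- build_shallow_orthography(10, seed = 4)
  # one grapheme given two rules at (0.5, 0.5): (9 + 0.5) / 10
  tab$rules$prob[1] <- 0.5
  tab$rules <- rbind(tab$rules, data.frame(
    grapheme = tab$rules$grapheme[1], phoneme = tab$rules$phoneme[2],
    prob = 0.5, context = NA_character_))
  expect_equal(consistency_index(tab), 0.95)
  tab$rules <- tab$rules[rev(seq_len(nrow(tab$rules))), ]
  expect_equal(consistency_index(tab), 0.95)
})

test_that("depth monotonicity: consistency decreases as depth increases", {
  for (seed in 1:5) {
    ci <- vapply(c(0.2, 0.5, 0.8, 1), function(d)
      consistency_index(build_deep_orthography(20, d, seed = seed)),
      numeric(1))
    expect_true(all(diff(ci) < 0))
    expect_lt(ci[1], 1)
  }
})

test_that("lexicons are Zipfian, self-consistent and deterministic", {
  tab <- build_shallow_orthography(12, seed = 5)
  cfg <- corpus_config(n_words = 100, zipf_exponent = 1, seed = 7)
  lex <- generate_lexicon(tab, cfg)
  expect_equal(nrow(lex), 100)
  expect_false(anyDuplicated(lex$spelling) > 0)
  expect_equal(lex$frequency[1] / lex$frequency[2], 2)       # Zipf s=1
  expect_equal(sum(lex$frequency / 1e6), 1, tolerance = 1e-9)
  # entry invariants: segmentation concatenates; rules yield pronunciation
  for (i in seq_len(nrow(lex))) {
    expect_equal(paste(lex$segmentation[[i]], collapse = ""), lex$spelling[i])
    for (j in seq_along(lex$segmentation[[i]])) {
      allowed <- tab$rules$phoneme[tab$rules$grapheme == lex$segmentation[[i]][j]]
      expect_true(lex$pronunciation[[i]][j] %in% allowed)
    }
  }
  expect_identical(lex, generate_lexicon(tab, cfg))
})

test_that("only deep lexicons contain ambiguous spellings", {
  shallow <- build_shallow_orthography(12, seed = 6)
  lexs <- generate_lexicon(shallow, corpus_config(n_words = 60, seed = 8))
  expect_equal(count_ambiguous_spellings(lexs, shallow), 0)

  deep <- build_deep_orthography(12, 1, seed = 6)
  lexd <- generate_lexicon(deep, corpus_config(n_words = 60, seed = 8))
  expect_gte(count_ambiguous_spellings(lexd, deep), 1)
})

test_that("pseudo-words are non-lexical, structure-preserving and correctly enumerated", {
  tab <- build_shallow_orthography(12, seed = 9)
  lex <- generate_lexicon(tab, corpus_config(n_words = 80, seed = 10))
  psw <- generate_pseudowords(lex, tab, 30, seed = 11)
  expect_equal(nrow(psw), 30)
  expect_length(intersect(psw$spelling, lex$spelling), 0)
  n_vowels <- function(seg, tb) sum(grapheme_class_of(tb, seg) == "vowel")
  for (i in seq_len(nrow(psw))) {
    expect_equal(n_vowels(psw$segmentation[[i]], tab), 2)  # disyllabic
    expect_length(psw$acceptable[[i]], 1)                  # shallow: unique
  }

  # deep table: an item with one two-rule grapheme has exactly two readings
  deep <- tiny_deep_table()
  segs <- list(c("t", "a", "s", "a"))
  pr <- enumerate_pronunciations(segs[[1]], deep)
  expect_length(pr, 2)
  expect_setequal(vapply(pr, `[`, character(1), 1), c("toyd_p3", "toyd_p4"))
})

test_that("shared_graphemes is plain set intersection", {
  a <- tiny_table("A")
  b <- tiny_table("B")
  expect_setequal(shared_graphemes(a, a), a$graphemes$grapheme)
  b2 <- b
  b2$graphemes$grapheme <- c("x", "y", "z", "w", "v", "u")
  b2$rules$grapheme <- b2$graphemes$grapheme
  expect_length(shared_graphemes(a, b2), 0)
  b3 <- b
  b3$graphemes$grapheme[1] <- "x"
  b3$rules$grapheme[1] <- "x"
  expect_setequal(shared_graphemes(a, b3), c("e", "t", "s", "k", "b"))
})

test_that("language pairs share graphemes and counterpart phoneme features", {
  pair <- build_language_pair(20, 0.6, seed = 12)
  expect_setequal(pair$shallow$graphemes$grapheme,
                  pair$deep$graphemes$grapheme)
  n <- nrow(pair$shallow$phonemes)
  # counterpart phonemes (same index) at Hamming distance 0
  for (i in seq_len(n))
    expect_equal(phoneme_distance(pair$shallow$features[i, ],
                                  pair$deep$features[i, ]), 0)
  # all other cross-language pairs at distance >= 2
  d <- as.matrix(dist(rbind(pair$shallow$features,
                            pair$deep$features[seq_len(n), ]),
                      method = "manhattan"))
  cross <- d[seq_len(n), n + seq_len(n)]
  expect_true(all(cross[row(cross) != col(cross)] >= 2))
  # the deep language's inventory is strictly larger
  expect_gt(nrow(pair$deep$phonemes), n)
})

test_that("lexicon and stimulus files round-trip losslessly", {
  tab <- build_shallow_orthography(12, seed = 13)
  lex <- generate_lexicon(tab, corpus_config(n_words = 40, seed = 14))
  f <- tempfile(fileext = ".tsv")
  write_lexicon(lex, f)
  lex2 <- read_lexicon(f)
  expect_equal(lex2$spelling, lex$spelling)
  expect_equal(lex2$segmentation, lex$segmentation)
  expect_equal(lex2$pronunciation, lex$pronunciation)
  expect_equal(lex2$frequency, lex$frequency, tolerance = 1e-12)

  stim <- rbind(sample_word_stimuli(lex, tab, 10, seed = 15),
                generate_pseudowords(lex, tab, 10, seed = 16))
  g <- tempfile(fileext = ".tsv")
  write_stimuli(stim, g)
  stim2 <- read_stimuli(g)
  expect_equal(stim2$spelling, stim$spelling)
  expect_equal(stim2$lexicality, stim$lexicality)
  expect_equal(stim2$acceptable, stim$acceptable)
  unlink(c(f, g))
})
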
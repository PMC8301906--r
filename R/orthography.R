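#' @useDynLib orthosim, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rlnorm rpois pt pchisq sd vcov wilcox.test
#' @importFrom utils head read.delim write.table
NULL

VOWEL_LETTERS <- c("a", "e", "i", "o", "u")
CONSONANT_LETTERS <- setdiff(letters, VOWEL_LETTERS)

#' Construct a grapheme-phoneme mapping table
#'
#' A mapping table describes one artificial orthography: its grapheme
#' inventory (split into vowel and consonant graphemes), its phoneme
#' inventory with binary articulatory feature vectors, and a rule set of
#' grapheme-to-phoneme correspondences with probabilities.  Orthographic
#' depth lives entirely in the rule set: a shallow table has exactly one
#' rule per grapheme (a bijection), a deep table gives some graphemes
#' several alternative phonemes.
#'
#' @param language_id single string naming the language.
#' @param graphemes data frame with columns `grapheme`, `class`
#'   (`"vowel"` or `"consonant"`).
#' @param phonemes data frame with columns `symbol`, `class`.
#' @param features binary matrix, one row per phoneme (rownames = symbols).
#' @param rules data frame with columns `grapheme`, `phoneme`, `prob`,
#'   `context` (`NA` for unconditional rules).
#' @return an object of class `mapping_table`.
#' @export
mapping_table <- function(language_id, graphemes, phonemes, features, rules) {
  stopifnot(is.character(language_id), length(language_id) == 1L)
  stopifnot(!anyDuplicated(graphemes$grapheme), !anyDuplicated(phonemes$symbol))
  stopifnot(nrow(features) == nrow(phonemes))
  rownames(features) <- phonemes$symbol
  if (!all(graphemes$grapheme %in% rules$grapheme))
    stop("every grapheme must appear in at least one rule")
  if (!all(rules$phoneme %in% phonemes$symbol))
    stop("rules refer to unknown phonemes")
  psum <- tapply(rules$prob, paste(rules$grapheme, rules$context %|NA|% ""), sum)
  if (any(abs(psum - 1) > 1e-9))
    stop("rule probabilities must sum to 1 per (grapheme, context)")
  structure(
    list(language_id = language_id, graphemes = graphemes,
         phonemes = phonemes, features = features, rules = rules),
    class = "mapping_table")
}

`%|NA|%` <- function(x, repl) ifelse(is.na(x), repl, x)

#' @exportS3Method base::print
print.mapping_table <- function(x, ...) {
  cat(sprintf(
    "<mapping_table '%s'>: %d graphemes, %d phonemes, %d rules, consistency %.3f\n",
    x$language_id, nrow(x$graphemes), nrow(x$phonemes), nrow(x$rules),
    consistency_index(x)))
  invisible(x)
}

grapheme_class <- function(table, graphemes) {
  table$graphemes$class[match(graphemes, table$graphemes$grapheme)]
}

## Distinct binary feature vectors with pairwise Hamming distance >= 2,
## so that only deliberately constructed counterparts sit at distance 0.
make_feature_bank <- function(n, feature_len) {
  if (feature_len < 4) stop("feature_len must be at least 4")
  bank <- matrix(NA_integer_, 0, feature_len)
  tries <- 0L
  while (nrow(bank) < n) {
    cand <- as.integer(runif(feature_len) > 0.5)
    ok <- nrow(bank) == 0L ||
      all(colSums(abs(t(bank) - cand)) >= 2)
    if (ok) bank <- rbind(bank, cand)
    tries <- tries + 1L
    if (tries > 1000L * n)
      stop("feature space too small for ", n, " phonemes at distance >= 2")
  }
  bank
}

## Allocate grapheme strings: single letters first, then digraphs within
## the same letter class, so greedy segmentation stays well behaved.
allocate_graphemes <- function(n_vowel, n_consonant) {
  vow <- VOWEL_LETTERS
  if (n_vowel > length(vow)) {
    digr <- as.vector(outer(VOWEL_LETTERS, VOWEL_LETTERS, paste0))
    vow <- c(vow, setdiff(digr, vow))
  }
  if (n_vowel > length(vow)) stop("grapheme space exhausted for vowels")
  con <- CONSONANT_LETTERS
  if (n_consonant > length(con)) {
    digr <- as.vector(outer(CONSONANT_LETTERS, c("h", "r", "l"), paste0))
    con <- c(con, setdiff(digr, con))
  }
  if (n_consonant > length(con)) stop("grapheme space exhausted for consonants")
  list(vowel = vow[seq_len(n_vowel)], consonant = con[seq_len(n_consonant)])
}

shallow_components <- function(n_graphemes, feature_len, language_id,
                               features = NULL) {
  if (n_graphemes < 4) stop("need at least 4 graphemes")
  n_vowel <- max(2L, round(n_graphemes / 4))
  n_consonant <- n_graphemes - n_vowel
  if (n_consonant < 2) stop("need at least 2 consonant graphemes")
  gr <- allocate_graphemes(n_vowel, n_consonant)
  graphemes <- data.frame(
    grapheme = c(gr$vowel, gr$consonant),
    class = rep(c("vowel", "consonant"), c(n_vowel, n_consonant)),
    stringsAsFactors = FALSE)
  phonemes <- data.frame(
    symbol = sprintf("%s_p%02d", language_id, seq_len(n_graphemes)),
    class = graphemes$class, stringsAsFactors = FALSE)
  if (is.null(features)) features <- make_feature_bank(n_graphemes, feature_len)
  list(graphemes = graphemes, phonemes = phonemes, features = features)
}

#' Build a shallow (fully consistent) artificial orthography
#'
#' One grapheme maps to exactly one phoneme and vice versa, the analogue
#' of a transparent alphabetic orthography.  [consistency_index()] of the
#' result is exactly 1.
#'
#' @param n_graphemes total inventory size (>= 4); about a quarter are
#'   vowel graphemes.
#' @param feature_len length of the binary phoneme feature vectors.
#' @param seed RNG seed; identical seeds give identical tables.
#' @param language_id label stored in the table.
#' @param features optional pre-built phoneme feature matrix; used to give
#'   two languages counterpart phonemes at Hamming distance 0.
#' @return a [mapping_table()].
#' @export
build_shallow_orthography <- function(n_graphemes, feature_len = 8, seed = 1,
                                      language_id = "shallow",
                                      features = NULL) {
  set.seed(seed)
  cmp <- shallow_components(n_graphemes, feature_len, language_id, features)
  rules <- data.frame(
    grapheme = cmp$graphemes$grapheme, phoneme = cmp$phonemes$symbol,
    prob = 1, context = NA_character_, stringsAsFactors = FALSE)
  mapping_table(language_id, cmp$graphemes, cmp$phonemes, cmp$features, rules)
}

#' Build a deep (inconsistent) artificial orthography
#'
#' Starts from a one-to-one base mapping and gives a fraction
#' `depth_level` of the graphemes a second, alternative phoneme rule.
#' Half of the alternatives point to phonemes the language does not
#' otherwise use (enlarging its phoneme inventory, the way a deep
#' orthography's sound set outgrows a shallow one's), the other half to
#' existing same-class phonemes, so that some letters stand for several
#' sounds and some sounds are reachable from several letters.
#'
#' @inheritParams build_shallow_orthography
#' @param depth_level fraction of graphemes in (0, 1] receiving a second
#'   rule; `round(depth_level * n_graphemes)` graphemes become ambiguous.
#' @param dominant_prob probability of the dominant rule of an ambiguous
#'   grapheme (the alternative gets `1 - dominant_prob`).
#' @param features optional feature matrix for the base (counterpart)
#'   phonemes; extra alternative-target phonemes always draw fresh
#'   feature vectors at Hamming distance >= 2 from every other phoneme.
#' @return a [mapping_table()] with [consistency_index()] < 1.
#' @export
build_deep_orthography <- function(n_graphemes, depth_level, feature_len = 8,
                                   seed = 1, language_id = "deep",
                                   features = NULL, dominant_prob = 0.7) {
  if (depth_level <= 0)
    stop("depth_level must be > 0; use build_shallow_orthography() for a fully consistent table")
  stopifnot(depth_level <= 1, dominant_prob > 0.5, dominant_prob < 1)
  set.seed(seed)
  cmp <- shallow_components(n_graphemes, feature_len, language_id, features)
  n_multi <- round(depth_level * n_graphemes)
  multi <- sort(sample(seq_len(n_graphemes), n_multi))
  ## alternative targets: alternately an extra (deep-only) phoneme of the
  ## grapheme's class, or an existing same-class phoneme
  phonemes <- cmp$phonemes
  feat <- cmp$features
  extras <- list(vowel = integer(0), consonant = integer(0))
  alt_rows <- vector("list", length(multi))
  to_extra <- rep(c(TRUE, FALSE), length.out = length(multi))
  for (k in seq_along(multi)) {
    i <- multi[k]
    cls <- cmp$graphemes$class[i]
    if (to_extra[k]) {
      ## extra phonemes are shared between two ambiguous graphemes of the
      ## same class, so some sounds are reachable from several letters
      pool <- extras[[cls]]
      reuse <- length(pool) > 0L &&
        sum(alt_rows_phoneme(alt_rows, phonemes$symbol[pool[length(pool)]])) < 2L
      if (reuse) {
        alt <- pool[length(pool)]
      } else {
        sym <- sprintf("%s_x%02d", language_id, nrow(phonemes) + 1L)
        new_feat <- new_distinct_feature(feat, ncol(feat))
        phonemes <- rbind(phonemes,
                          data.frame(symbol = sym, class = cls,
                                     stringsAsFactors = FALSE))
        feat <- rbind(feat, new_feat)
        alt <- nrow(phonemes)
        extras[[cls]] <- c(extras[[cls]], alt)
      }
    } else {
      same_class <- setdiff(which(phonemes$class == cls &
                                    seq_len(nrow(phonemes)) <= n_graphemes), i)
      alt <- sample(same_class, 1L)
    }
    alt_rows[[k]] <- data.frame(
      grapheme = cmp$graphemes$grapheme[i], phoneme = phonemes$symbol[alt],
      prob = 1 - dominant_prob, context = NA_character_,
      stringsAsFactors = FALSE)
  }
  rules <- data.frame(
    grapheme = cmp$graphemes$grapheme, phoneme = cmp$phonemes$symbol,
    prob = 1, context = NA_character_, stringsAsFactors = FALSE)
  rules$prob[multi] <- dominant_prob
  rules <- rbind(rules, do.call(rbind, alt_rows))
  rownames(feat) <- phonemes$symbol
  mapping_table(language_id, cmp$graphemes, phonemes, feat, rules)
}

alt_rows_phoneme <- function(alt_rows, symbol) {
  vapply(alt_rows, function(r) !is.null(r) && r$phoneme == symbol, logical(1))
}

## A fresh binary feature vector at Hamming distance >= 2 from every row.
new_distinct_feature <- function(bank, feature_len) {
  for (try in seq_len(20000L)) {
    cand <- as.integer(runif(feature_len) > 0.5)
    if (all(colSums(abs(t(bank) - cand)) >= 2)) return(cand)
  }
  stop("feature space exhausted")
}

#' Build a shallow/deep language pair with counterpart phonemes
#'
#' The two tables share the same grapheme inventory and their phonemes
#' are pairwise counterparts with identical feature vectors (Hamming
#' distance 0), the configuration used by the cross-orthography transfer
#' experiments.
#'
#' @inheritParams build_deep_orthography
#' @return list with elements `shallow` and `deep`.
#' @export
build_language_pair <- function(n_graphemes, depth_level = 0.6,
                                feature_len = 8, seed = 1) {
  set.seed(seed)
  bank <- make_feature_bank(n_graphemes, feature_len)
  shallow <- build_shallow_orthography(
    n_graphemes, feature_len, seed = seed + 1L,
    language_id = "shallow", features = bank)
  deep <- build_deep_orthography(
    n_graphemes, depth_level, feature_len, seed = seed + 2L,
    language_id = "deep", features = bank)
  list(shallow = shallow, deep = deep)
}

#' Consistency index of a mapping table
#'
#' Scalar summary of orthographic depth: the mean, over graphemes, of the
#' maximum rule probability of that grapheme.  A bijective table scores
#' exactly 1; adding any alternative rule strictly lowers the score.
#'
#' @param table a [mapping_table()].
#' @return number in (0, 1].
#' @export
consistency_index <- function(table) {
  stopifnot(inherits(table, "mapping_table"))
  if (nrow(table$rules) == 0L) stop("empty mapping table")
  mx <- tapply(table$rules$prob, table$rules$grapheme, max)
  mean(mx[table$graphemes$grapheme])
}

#' Graphemes shared by two orthographies
#'
#' @param table_a,table_b [mapping_table()] objects.
#' @return character vector: the intersection of the two grapheme
#'   inventories.
#' @export
shared_graphemes <- function(table_a, table_b) {
  intersect(table_a$graphemes$grapheme, table_b$graphemes$grapheme)
}

#' Hamming distance between two phoneme feature vectors
#'
#' Closeness of phonemes across languages is measured in a shared binary
#' articulatory feature space; "featurally close" phonemes (distance at
#' most `tau` of the transfer configuration) receive transferred weights.
#'
#' @param p,q binary feature vectors of equal length (or lists with a
#'   `features` element).
#' @return integer Hamming distance; 0 iff identical.
#' @export
phoneme_distance <- function(p, q) {
  if (is.list(p)) p <- p$features
  if (is.list(q)) q <- q$features
  if (length(p) != length(q)) stop("feature vectors differ in length")
  sum(p != q)
}
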
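#' Corpus generation settings
#'
#' @param n_words number of lexicon entries (>= 10).
#' @param zipf_exponent Zipf exponent `s`: the frequency of the word of
#'   rank `r` is proportional to `1 / r^s`.
#' @param seed RNG seed.
#' @param max_onset,max_cluster,max_coda limits on generated word shapes:
#'   word-initial onset size, intervocalic cluster size, word-final coda
#'   size (in consonant graphemes).
#' @return an object of class `corpus_config`.
#' @export
corpus_config <- function(n_words = 500, zipf_exponent = 1, seed = 1,
                          max_onset = 2, max_cluster = 2, max_coda = 1) {
  stopifnot(n_words >= 10, zipf_exponent > 0)
  structure(list(n_words = as.integer(n_words), zipf_exponent = zipf_exponent,
                 seed = as.integer(seed), max_onset = as.integer(max_onset),
                 max_cluster = as.integer(max_cluster),
                 max_coda = as.integer(max_coda)),
            class = "corpus_config")
}

## Pronunciations of ambiguous graphemes are drawn from the rule
## probabilities once per (grapheme, following grapheme) type and then
## reused, so the corpus realises a type-consistent, context-conditioned
## inconsistency (as in English, where the reading of an ambiguous
## letter is largely predictable from its orthographic neighbourhood)
## rather than per-token noise no reader could learn.
sample_pronunciation <- function(segmentation, table, digraph_env = NULL) {
  n <- length(segmentation)
  vapply(seq_len(n), function(i) {
    g <- segmentation[i]
    r <- table$rules[table$rules$grapheme == g, ]
    if (nrow(r) == 1L) return(r$phoneme)
    if (is.null(digraph_env))
      return(sample(r$phoneme, 1L, prob = r$prob))
    key <- paste(g, if (i < n) segmentation[i + 1L] else "#")
    hit <- digraph_env[[key]]
    if (is.null(hit)) {
      hit <- sample(r$phoneme, 1L, prob = r$prob)
      digraph_env[[key]] <- hit
    }
    hit
  }, character(1), USE.NAMES = FALSE)
}

#' Generate a Zipf-distributed disyllabic lexicon
#'
#' Draws `n_words` unique disyllabic spellings over the table's
#' inventory (onset consonants + vowel, optional intervocalic cluster,
#' optional final coda), samples each word's pronunciation from the
#' table's rule probabilities, and attaches Zipfian token frequencies on
#' a nominal one-million-token scale.  Every generated spelling is
#' guaranteed to re-segment (greedy longest match) into its generating
#' grapheme sequence and to fit the slot template.
#'
#' @param table a [mapping_table()].
#' @param cfg a [corpus_config()].
#' @param template a [slot_template()]; defaults to the standard
#'   disyllabic template.
#' @return a [tibble::tibble] with columns `spelling`, `segmentation`
#'   (list), `pronunciation` (list), `frequency`, `rank`.
#' @export
generate_lexicon <- function(table, cfg, template = slot_template()) {
  set.seed(cfg$seed)
  vow <- table$graphemes$grapheme[table$graphemes$class == "vowel"]
  con <- table$graphemes$grapheme[table$graphemes$class == "consonant"]
  if (length(vow) < 1L || length(con) < 1L)
    stop("inventory must contain vowel and consonant graphemes")
  seen <- new.env(hash = TRUE)
  digraphs <- new.env(hash = TRUE)
  words <- vector("list", cfg$n_words)
  n_ok <- 0L
  attempts <- 0L
  max_attempts <- 200L * cfg$n_words
  while (n_ok < cfg$n_words) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("grapheme inventory too small to form ", cfg$n_words,
           " unique disyllabic spellings")
    seg <- c(sample(con, sample(0:cfg$max_onset, 1L), replace = TRUE),
             sample(vow, 1L),
             sample(con, sample(0:cfg$max_cluster, 1L), replace = TRUE),
             sample(vow, 1L),
             sample(con, sample(0:cfg$max_coda, 1L), replace = TRUE))
    spelling <- paste(seg, collapse = "")
    if (!is.null(seen[[spelling]])) next
    ok <- tryCatch({
      identical(segment(spelling, table), seg) &&
        { assign_slots(seg, template, table); TRUE }
    }, error = function(e) FALSE)
    if (!ok) next
    seen[[spelling]] <- TRUE
    n_ok <- n_ok + 1L
    words[[n_ok]] <- list(spelling = spelling, segmentation = seg,
                          pronunciation = sample_pronunciation(seg, table,
                                                               digraphs))
  }
  s <- cfg$zipf_exponent
  raw <- 1 / seq_len(cfg$n_words)^s
  tibble::tibble(
    spelling = vapply(words, `[[`, character(1), "spelling"),
    segmentation = lapply(words, `[[`, "segmentation"),
    pronunciation = lapply(words, `[[`, "pronunciation"),
    frequency = 1e6 * raw / sum(raw),
    rank = seq_len(cfg$n_words))
}

#' Enumerate all rule-consistent pronunciations of a grapheme sequence
#'
#' Cartesian product of the applicable rules of each grapheme; for a
#' shallow table this is always a single pronunciation.
#'
#' @param segmentation character vector of graphemes.
#' @param table a [mapping_table()].
#' @return list of phoneme-symbol vectors.
#' @export
enumerate_pronunciations <- function(segmentation, table) {
  per <- lapply(segmentation, function(g)
    table$rules$phoneme[table$rules$grapheme == g])
  if (prod(lengths(per)) > 10000) stop("pronunciation space too large")
  grid <- expand.grid(rev(per), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)),
         function(i) rev(unlist(grid[i, ], use.names = FALSE)))
}

#' Count lexicon entries whose spelling admits several pronunciations
#'
#' A shallow orthography yields none; a deep one yields entries whose
#' spelling is compatible with two or more rule-consistent
#' pronunciations (the sense in which the same written form can be read
#' in different ways).
#'
#' @param lexicon from [generate_lexicon()].
#' @param table the generating [mapping_table()].
#' @return integer count.
#' @export
count_ambiguous_spellings <- function(lexicon, table) {
  sum(vapply(lexicon$segmentation, function(seg)
    length(enumerate_pronunciations(seg, table)) > 1L, logical(1)))
}

#' Generate pseudo-word stimuli from a lexicon
#'
#' Each pseudo-word is derived from a sampled lexicon word by replacing
#' one or two graphemes with other graphemes of the same class (vowel
#' for vowel, consonant for consonant), which preserves the syllabic
#' structure of the source word; the result must not be (or become) a
#' lexical spelling.  The acceptable pronunciations of each item are all
#' rule-consistent pronunciations under the table.
#'
#' @param lexicon from [generate_lexicon()].
#' @param table a [mapping_table()].
#' @param n number of pseudo-words.
#' @param seed RNG seed.
#' @param max_retries attempts per drawn source word before failing.
#' @return stimulus tibble: `spelling`, `lexicality`, `language_id`,
#'   `segmentation` (list), `acceptable` (list of pronunciation lists).
#' @export
generate_pseudowords <- function(lexicon, table, n, seed = 1,
                                 max_retries = 200) {
  stopifnot(nrow(lexicon) > 0)
  set.seed(seed)
  lex_spellings <- new.env(hash = TRUE)
  for (sp in lexicon$spelling) lex_spellings[[sp]] <- TRUE
  out <- vector("list", n)
  made <- new.env(hash = TRUE)
  for (i in seq_len(n)) {
    src <- lexicon[sample.int(nrow(lexicon), 1L), ]
    seg0 <- src$segmentation[[1L]]
    found <- FALSE
    for (try in seq_len(max_retries)) {
      seg <- seg0
      n_sub <- sample(1:2, 1L)
      pos <- sample(seq_along(seg), min(n_sub, length(seg)))
      for (p in pos) {
        cls <- grapheme_class(table, seg[p])
        alt <- setdiff(
          table$graphemes$grapheme[table$graphemes$class == cls], seg[p])
        if (length(alt) == 0L) next
        seg[p] <- if (length(alt) == 1L) alt else sample(alt, 1L)
      }
      spelling <- paste(seg, collapse = "")
      ok <- is.null(lex_spellings[[spelling]]) && is.null(made[[spelling]]) &&
        tryCatch({
          identical(segment(spelling, table), seg) &&
            { assign_slots(seg, slot_template(), table); TRUE }
        }, error = function(e) FALSE)
      if (ok) {
        made[[spelling]] <- TRUE
        out[[i]] <- list(spelling = spelling, segmentation = seg)
        found <- TRUE
        break
      }
    }
    if (!found)
      stop("could not derive a non-word from source word '", src$spelling, "'")
  }
  tibble::tibble(
    spelling = vapply(out, `[[`, character(1), "spelling"),
    lexicality = "pseudoword",
    language_id = table$language_id,
    segmentation = lapply(out, `[[`, "segmentation"),
    acceptable = lapply(out, function(w)
      enumerate_pronunciations(w$segmentation, table)))
}

#' Build a word stimulus set from a lexicon
#'
#' Samples `n` distinct lexicon words; each item's acceptable set is
#' exactly its lexical pronunciation.
#'
#' @inheritParams generate_pseudowords
#' @param n number of word stimuli.
#' @return stimulus tibble in the same format as
#'   [generate_pseudowords()].
#' @export
sample_word_stimuli <- function(lexicon, table, n, seed = 1) {
  stopifnot(n <= nrow(lexicon))
  set.seed(seed)
  idx <- sample.int(nrow(lexicon), n)
  tibble::tibble(
    spelling = lexicon$spelling[idx],
    lexicality = "word",
    language_id = table$language_id,
    segmentation = lexicon$segmentation[idx],
    acceptable = lapply(lexicon$pronunciation[idx], list))
}

#' Read and write lexicon files
#'
#' Tab-separated UTF-8 with header: `spelling`,
#' `grapheme_segmentation` (graphemes joined by "."), `pronunciation`
#' (phoneme symbols joined by "."), `frequency`.
#'
#' @param lexicon lexicon tibble.
#' @param path file path.
#' @return `read_lexicon()` returns the lexicon tibble;
#'   `write_lexicon()` its path, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  df <- data.frame(
    spelling = lexicon$spelling,
    grapheme_segmentation = vapply(lexicon$segmentation, paste,
                                   character(1), collapse = "."),
    pronunciation = vapply(lexicon$pronunciation, paste,
                           character(1), collapse = "."),
    frequency = lexicon$frequency)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_lexicon
#' @export
read_lexicon <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  tibble::tibble(
    spelling = df$spelling,
    segmentation = strsplit(df$grapheme_segmentation, ".", fixed = TRUE),
    pronunciation = strsplit(df$pronunciation, ".", fixed = TRUE),
    frequency = df$frequency,
    rank = seq_len(nrow(df)))
}

#' Read and write stimulus files
#'
#' Tab-separated UTF-8 with header: `spelling`, `lexicality`,
#' `language_id`, `acceptable_pronunciations` (";"-separated,
#' "."-joined phoneme lists), `grapheme_segmentation`.
#'
#' @param stimuli stimulus tibble.
#' @param path file path.
#' @return `read_stimuli()` returns the stimulus tibble;
#'   `write_stimuli()` its path, invisibly.
#' @export
write_stimuli <- function(stimuli, path) {
  df <- data.frame(
    spelling = stimuli$spelling,
    lexicality = stimuli$lexicality,
    language_id = stimuli$language_id,
    acceptable_pronunciations = vapply(stimuli$acceptable, function(a)
      paste(vapply(a, paste, character(1), collapse = "."), collapse = ";"),
      character(1)),
    grapheme_segmentation = vapply(stimuli$segmentation, paste,
                                   character(1), collapse = "."))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_stimuli
#' @export
read_stimuli <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  tibble::tibble(
    spelling = df$spelling,
    lexicality = df$lexicality,
    language_id = df$language_id,
    segmentation = strsplit(df$grapheme_segmentation, ".", fixed = TRUE),
    acceptable = lapply(strsplit(df$acceptable_pronunciations, ";", fixed = TRUE),
                        function(v) strsplit(v, ".", fixed = TRUE)))
}
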
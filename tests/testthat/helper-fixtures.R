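# Tiny hand-built fixtures and independent oracles used across tests.

# A fully explicit 6-grapheme shallow table (2 vowels, 4 consonants).
tiny_table <- function(language_id = "toy") {
  graphemes <- data.frame(
    grapheme = c("a", "e", "t", "s", "k", "b"),
    class = c("vowel", "vowel", rep("consonant", 4)),
    stringsAsFactors = FALSE)
  phonemes <- data.frame(
    symbol = paste0(language_id, "_p", 1:6),
    class = graphemes$class, stringsAsFactors = FALSE)
  features <- rbind(
    c(0, 0, 0, 0), c(1, 1, 0, 0), c(0, 0, 1, 1),
    c(1, 1, 1, 1), c(1, 0, 0, 1), c(0, 1, 1, 0))
  rules <- data.frame(grapheme = graphemes$grapheme,
                      phoneme = phonemes$symbol, prob = 1,
                      context = NA_character_, stringsAsFactors = FALSE)
  mapping_table(language_id, graphemes, phonemes, features, rules)
}

# tiny_table() with one ambiguous grapheme: "t" reads p3 (0.6) or p4 (0.4).
tiny_deep_table <- function() {
  tab <- tiny_table("toyd")
  tab$rules$prob[tab$rules$grapheme == "t"] <- 0.6
  tab$rules <- rbind(tab$rules, data.frame(
    grapheme = "t", phoneme = "toyd_p4", prob = 0.4,
    context = NA_character_, stringsAsFactors = FALSE))
  tab
}

# A four-word consistent toy corpus over tiny_table().
toy_lexicon <- function(tab = tiny_table()) {
  segs <- list(c("t", "a", "s", "a"), c("s", "e", "t", "a"),
               c("k", "a", "b", "e"), c("b", "e", "k", "a"))
  pron <- lapply(segs, function(s)
    tab$rules$phoneme[match(s, tab$rules$grapheme)])
  tibble::tibble(
    spelling = vapply(segs, paste, character(1), collapse = ""),
    segmentation = segs, pronunciation = pron,
    frequency = c(400, 300, 200, 100) * 1e3,
    rank = 1:4)
}

words_as_stimuli <- function(lexicon, tab) {
  tibble::tibble(spelling = lexicon$spelling, lexicality = "word",
                 language_id = tab$language_id,
                 segmentation = lexicon$segmentation,
                 acceptable = lapply(lexicon$pronunciation, list))
}

# Brute-force enumeration of all segmentations of a spelling over an
# inventory; used as the oracle for the greedy longest-match parser.
all_segmentations <- function(spelling, inventory) {
  if (nchar(spelling) == 0L) return(list(character(0)))
  out <- list()
  for (g in inventory) {
    if (startsWith(spelling, g)) {
      rest <- all_segmentations(substring(spelling, nchar(g) + 1L), inventory)
      out <- c(out, lapply(rest, function(r) c(g, r)))
    }
  }
  out
}

# Greedy-equivalent choice among all segmentations: lexicographically
# prefer the longer grapheme at the earliest position.
greedy_oracle <- function(spelling, inventory) {
  segs <- all_segmentations(spelling, inventory)
  if (length(segs) == 0L) return(NULL)
  best <- segs[[1L]]
  for (s in segs[-1L]) {
    n <- min(length(best), length(s))
    for (i in seq_len(n)) {
      if (nchar(s[i]) != nchar(best[i])) {
        if (nchar(s[i]) > nchar(best[i])) best <- s
        break
      }
    }
  }
  best
}

# Minimum-norm least-squares oracle for the linear read-out: W = T X^+.
ls_oracle <- function(net, lexicon, tab) {
  enc <- orthosim:::encode_lexicon(lexicon, tab, net$template)
  n <- nrow(lexicon)
  X <- matrix(0, ncol(net$W), n)
  T_ <- matrix(0, nrow(net$W), n)
  for (i in seq_len(n)) {
    X[enc$act_in[, i], i] <- 1
    T_[enc$act_out[, i], i] <- 1
  }
  T_ %*% MASS::ginv(X)
}

# Exact two-sided Mann-Whitney p by full enumeration of rank
# assignments (small n only).
mw_exact_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  stat <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - nx * (nx + 1) / 2
  }
  obs <- stat(seq_len(nx))
  combs <- utils::combn(nx + ny, nx)
  us <- apply(combs, 2, function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - nx * (nx + 1) / 2
  })
  mu <- nx * ny / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

grapheme_class_of <- function(tab, g)
  tab$graphemes$class[match(g, tab$graphemes$grapheme)]

quiet <- function(expr) suppressWarnings(suppressMessages(expr))
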
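#!/usr/bin/env Rscript
# Build the synthetic language pair and its corpora, and summarise what
# makes the two orthographies different: consistency, ambiguity, and
# inventory size.  Writes the lexicons and stimulus sets used by the
# later stages under results/.

suppressPackageStartupMessages(library(orthosim))
dir.create("results", showWarnings = FALSE)

seed <- 20260920L
pair <- build_language_pair(n_graphemes = 20, depth_level = 0.6, seed = seed)
template <- slot_template()

cat("Orthography summary\n")
for (lang in names(pair)) {
  tab <- pair[[lang]]
  cat(sprintf(
    "  %-8s %d graphemes, %d phonemes, %d rules, consistency index %.3f\n",
    lang, nrow(tab$graphemes), nrow(tab$phonemes), nrow(tab$rules),
    consistency_index(tab)))
}
cat("  shared graphemes:", length(shared_graphemes(pair$shallow, pair$deep)),
    "\n\n")

lex <- list()
for (lang in names(pair)) {
  lex[[lang]] <- generate_lexicon(pair[[lang]],
                                  corpus_config(n_words = 100, seed = seed + 1L),
                                  template)
  write_lexicon(lex[[lang]], file.path("results",
                                       paste0("lexicon_", lang, ".tsv")))
  amb <- count_ambiguous_spellings(lex[[lang]], pair[[lang]])
  cat(sprintf(
    "%s lexicon: %d words, top frequency %.0f per million, %d spellings with multiple readings\n",
    lang, nrow(lex[[lang]]), lex[[lang]]$frequency[1], amb))
}

cat("\nStimulus sets (40 words + 40 pseudo-words per language)\n")
for (lang in names(pair)) {
  stim <- rbind(
    sample_word_stimuli(lex[[lang]], pair[[lang]], 40, seed = seed + 2L),
    generate_pseudowords(lex[[lang]], pair[[lang]], 40, seed = seed + 3L))
  write_stimuli(stim, file.path("results", paste0("stimuli_", lang, ".tsv")))
  multi <- mean(lengths(stim$acceptable[stim$lexicality == "pseudoword"]) > 1)
  cat(sprintf("  %-8s %d items; %.0f%% of pseudo-words have several acceptable readings\n",
              lang, nrow(stim), 100 * multi))
}

cat("\nWrote lexicons and stimulus files under results/.\n")
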
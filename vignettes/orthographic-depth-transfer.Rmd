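---
title: "Sequential learning of shallow and deep orthographies: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequential learning of shallow and deep orthographies: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthosim)
```

# The question

Alphabetic orthographies differ in how consistently letters map to
sounds: Italian-like *shallow* systems are close to one-to-one, while
English-like *deep* systems are many-to-many and context-dependent.
When a reader acquires a second orthography decades after the first,
does the consistency of the *first* orthography constrain what the
second can become?  `orthosim` studies this with the smallest model in
which the question is well-posed: a two-layer linear associative
network that learns grapheme-to-phoneme decoding by the delta rule, is
trained on one artificial orthography, and is then re-used — weights
and all — as the starting point for learning a second one.  A parallel
set of tools implements the reaction-time analysis pipeline such
naming experiments use on the human side.

# The decoding network

Input and output layers use **slot coding**.  A disyllabic item is
parsed into a fixed template of 12 slots (per syllable: three onset
slots, one vowel slot, two coda slots); each slot carries one unit per
grapheme (input side) or phoneme (output side) plus an explicit
"empty" unit, and exactly one unit per slot is active.  Graphemic
parsing is deterministic: greedy longest-match segmentation, then
vowel-anchored syllabification in which a single intervocalic
consonant joins the following onset while larger clusters give their
first consonant to the preceding coda (the split Italian disyllables
such as *tes.ta* show).  This replaces the serial graphemic parser of
large-scale reading models: the claims under study concern mapping
consistency, not parsing dynamics.

Learning is the delta rule,
$\Delta W = \eta\, (\mathbf{t} - W\mathbf{x})\, \mathbf{x}^\top$,
applied once per word presentation, with words sampled with
probability proportional to $\log(1 + \text{frequency})$ — the
standard compressed-frequency regime of large-scale reading
simulations.  With one-hot coding the update touches only the active
columns; the compiled core exploits this.  `train_config()` also
exposes an error dead band (units already within a tolerance of their
target are not updated); its default is 0, i.e. the pure delta rule,
which keeps an exact correspondence with the least-squares solution
(see *Numerical checks*).

**Naming latency** is read out as deterministic cycles-to-threshold
with competitive accumulation.  Per filled slot the winning phoneme
unit accumulates at drift $v - \max(0, r)$, where $v$ is the winner's
net input and $r$ the strongest competitor's; the item's latency is
the first cycle at which every filled slot has reached threshold
$\theta$, capped at `max_cycles`.  The competitive term matters: the
interference that cross-orthography transfer seeds loads *competing*
phoneme units, so a readout driven by the winner's input alone would
be structurally blind to it, while margins (winner minus runner-up)
causally determine speed here, as in interactive-activation accounts
of naming.  Defaults: $\theta = 1$, step $\varepsilon = 0.01$ (so a
clean unit-strength mapping yields 100 cycles), `max_cycles = 200`.
A reading is correct when every filled slot's winner matches one of
the item's acceptable pronunciations, slot-aligned.

# Synthetic orthographies

`build_language_pair()` constructs two orthographies over one shared
20-grapheme inventory (about a quarter vowels).  Phonemes carry binary
articulatory feature vectors; the two languages' phoneme inventories
are pairwise *counterparts* with identical features (Hamming distance
0), and all non-counterpart pairs are kept at distance two or more by
rejection sampling, so "featurally close" is exactly the counterpart
relation at the default transfer threshold $\tau = 0$.

The **shallow** language is a bijection: one rule per grapheme,
consistency index 1.  The **deep** language gives a fraction
`depth_level` (default 0.6) of graphemes a second rule with
probability 0.3.  Half of these alternatives map to *extra* phonemes
that only the deep language uses, mirroring the fact that deep
orthographies express larger sound-mapping inventories (English has
dozens more phonemes and hundreds more correspondences than Italian);
the other half map to existing same-class phonemes, so some sounds are
reachable from several letters.  The consistency index — the mean over
graphemes of their maximum rule probability — is 0.82 at the default
depth and decreases monotonically in `depth_level`.

**Lexicons** are Zipfian: 100 unique disyllabic words per language
(onset up to two consonant graphemes, optional intervocalic cluster,
optional final coda), rank-$r$ frequency proportional to $1/r^s$ with
$s = 1$, scaled to counts per million tokens.  Pronunciations of
ambiguous graphemes are drawn from the rule probabilities **once per
(grapheme, following-grapheme) type** and then reused across the
lexicon.  This makes the deep corpus a type-consistent, conditionally
inconsistent system — like English, where a letter's reading is
largely predictable from its orthographic neighbourhood — rather than
token-level noise that no reader could learn (under per-token
sampling, deep word accuracy is capped near the dominant-rule rate,
about 0.55 at these settings).

**Corpus scale** is a deliberate choice.  With 20 graphemes, a corpus
of several hundred words attests every slot-grapheme combination many
times; the delta rule then converges to the unique least-squares map
on that span, first- and second-language networks become numerically
indistinguishable on every test item, and pseudo-words stop being
novel in any respect — an artifact of the scaled-down alphabet, not a
property of reading.  Real corpora never saturate a deep orthography's
mapping space, and the transfer phenomenon under study lives exactly
in the mappings a second-language corpus does *not* exercise.  The
default of 100 words keeps each slot-grapheme combination attested
only about four times on average, with a rare tail, preserving
pseudo-word novelty at this scale.  The saturated regime remains
available (`experiment_config(n_words = 500)`) and is instructive:
every latency contrast collapses there.

**Pseudo-words** substitute one or two graphemes of a sampled word
with same-class graphemes (consonant for consonant, vowel for vowel),
preserving syllable structure, and must not produce a lexical
spelling.  Their acceptable pronunciations are all rule-consistent
readings under the table — the same criterion human raters apply.

# The four-model experiment

`run_experiment()` trains, per the default study conditions:

| model | training | presentations | $\eta$ |
|---|---|---|---|
| L1-shallow | from zero | 300,000 | 0.05 |
| L1-deep | from zero | 300,000 | 0.05 |
| L2-shallow | seeded from L1-deep | 150,000 | 0.01 |
| L2-deep | seeded from L1-shallow | 300,000 | 0.01 |

Transfer copies, for every shared grapheme (and the structural empty
units), each nonzero weight onto every second-language phoneme within
feature distance $\tau$ of its source phoneme, in the same slot,
summing on collisions and scaling by `scale` (default 1); extra
deep-only phonemes have no counterpart within $\tau = 0$ and are
dropped.  The transfer mask records exactly the written entries.  The
second-language phase uses the smaller learning rate, and the deep-
as-second-language network trains twice as long as the shallow one,
reflecting the assumption that proficiency in the inconsistent
orthography takes longer to reach; `matched_training = TRUE` equates
all budgets at 300,000 for the sensitivity analysis.  Second-language
networks are tested only on their second orthography's stimuli
(blocked presentation; the model has no mechanism for switching
between orthographies).  Test sets are 40 words and 40 pseudo-words
per language, the human experiment's blocked-set sizes.

Weight analyses use `used_weights()` (entries with $|w| > \theta_w$,
default $\theta_w = 0.01$ — well below a converged unit-strength
mapping, above float noise) and `transfer_overlap_proportion()` (used
entries that the transfer wrote, among used entries).
`latency_contrast()` compares correct-trial latencies of the first-
and second-language model of one orthography by rank-sum test;
positive differences mean the second-language model is slower.

Across seeds the pattern is stable: the shallow orthography reaches
95% word accuracy in a fraction of the presentations the deep one
needs; the second-language shallow model is significantly slower than
its first-language counterpart on pseudo-words (and slightly so on
words), while the two deep models are statistically indistinguishable;
under matched training the word effect essentially vanishes but the
pseudo-word effect survives — novel strings keep probing transferred
mappings that the second-language corpus never cleaned up, whereas
trained words are corrected to convergence.  The deep network uses
about twice as many weights as the shallow one, transferred counts are
similar in both directions, and the proportion of used weights that
transfer seeded is higher in the shallow-after-deep network.  The
analysis scripts under `analysis/` and `scripts/acceptance.R`
recompute all of this.

# The reaction-time pipeline

`simulate_rt_dataset()` draws log-normal trial RTs with crossed
subject and item random intercepts
($\sigma_{\text{subj}} = 0.10$, $\sigma_{\text{item}} = 0.05$,
$\sigma_{\varepsilon} = 0.15$ on the log scale, typical of naming
data) over a two-group (first-language Italian vs English), two-
language, blocked/mixed design, 20 subjects per group and 20 items
per cell by default.  The default fixed effects are calibrated to the
published word-reading cell means of a two-group bilingual naming
experiment on the log-ms scale
(treatment coding; the group-by-task term, reported null there, is
fixed at zero), so the default dataset reproduces the qualitative
behavioural pattern: both groups read their first orthography faster,
the group difference is several times larger for Italian than English
stimuli, and blocked presentation benefits the Italian-native group's
first orthography most.  Voice-key failures (3.9%) and reading errors
(0.8%) are injected at the rates such experiments report.  What the
generator does **not** emulate: item-level psycholinguistic structure
(frequency, neighbourhood and bigram covariates are drawn
independently of the RTs, which is precisely what makes the
covariate-robustness check interpretable), attention drift, speed-
accuracy trade-offs, and any dependence of error rates on condition.
Passing tests therefore show that the *pipeline* is correct and
calibrated, not that these models fit any particular human dataset.

`exclude_trials()` applies the staged exclusion exactly in the order
such studies describe — voice-key failures, then inaccurate readings,
then raw RTs three or more SDs from the mean of the remaining set —
and returns a per-stage audit whose counts always sum back to the
input.  Whether the outlier criterion should apply per analysis set or
per cell is ambiguous in most method sections; the default is the
whole analysis set, with `per_cell = TRUE` available.

`fit_rt_model()` fits `log RT ~ language * group` (optionally
`* task`, plus stimulus covariates) with random intercepts for
subjects and stimuli — the random structure is intercepts-only because
maximal structures routinely fail to converge on data of this shape —
and computes the planned one-degree contrast, the difference of group
differences between Italian and English stimuli, as a linear
combination of fixed effects with covariates held at their means.  The
test uses Satterthwaite denominator degrees of freedom; at the default
design the contrast is residual-dominated, and 400-run null batteries
put its type-I error at about 0.055 at nominal 0.05.  Convergence
diagnostics are captured and returned, never swallowed.  Sign recovery
of an injected 0.05 log-unit interaction at 20 subjects per group and
40 items is essentially perfect.

`t_from_summary()` reproduces pooled-variance t tests from printed
(mean, SD, N) triples: with 22 and 18 participants the printed
`t(38)` values of such a study's demographic table reproduce to three
decimals, including their p values.  Two of that table's printed rows
(simple vocal RT, printed with df 41, and articulation speed) are not
arithmetically consistent with their own printed summaries and are not
asserted anywhere.  `rank_tests()` wraps the exact small-sample
Mann-Whitney/Wilcoxon machinery (exact for n of at most 12 without
ties, normal approximation otherwise), and `o1_advantage()` computes
the per-subject first-orthography advantage (second-orthography RT
minus first, positive = first orthography faster) with group-relative
labelling.

# Numerical checks and edge cases

* **Least-squares oracle.** On a small consistent corpus the trained
  weight matrix agrees elementwise (tolerance $10^{-2}$) with
  $T X^{+}$ computed by pseudoinverse, and the mean squared output
  error falls below $10^{-3}$; this pins the learning rule's
  correctness independently of the training loop's implementation.
* **Transfer identity.** Transferring a trained network onto its own
  language with $\tau = 0$, scale 1 reproduces the weights bit-exactly
  and marks exactly the nonzero entries.
* **Determinism.** Every generator and the whole experiment are
  deterministic given their seeds; the master seed derives all
  sub-seeds.
* **Ties and degenerate input.** An untrained network (all-zero net
  input) reads nothing: ties at zero never count as winners, latency
  is `max_cycles`.  Empty stimulus sets, all-tied rank-test input,
  non-positive RTs, zero pooled variance with unequal means, and
  fully-filtered trial tables all raise explicit errors.
* **Quantisation.** Latencies are integer cycles via ceiling, so net-
  input differences below about $10^{-2}$ relative are invisible; the
  step size was chosen so that a unit-strength mapping sits at 100
  cycles, half of `max_cycles`.

# Problem sizes

The shipped analyses use 100-word lexicons, 40 + 40 test items per
language, the presentation budgets in the table above, ten master
seeds for the robustness battery, 100 parameter-recovery fits at the
published design size and 400 reduced-size null fits (12 subjects per
group, 12 items per cell).  These sizes make every reported quantity
reproducible on a laptop in minutes while keeping the Monte-Carlo
error of each rate estimate well below the margins asserted for it.

# Known limitations

The network is linear and sublexical: no lexical route, no feedback,
no stress assignment, and no mechanism for mixed-language
presentation, so only blocked reading is simulated.  Orthographic
depth is realised as probabilistic two-way ambiguity plus inventory
expansion; real deep orthographies also have multi-letter context
rules and morphological conditioning.  The latency readout is a
deterministic accumulator, so it cannot produce RT variability within
an item.  And the synthetic languages are matched by construction in
everything except consistency — which is the point of the design, but
means quantitative latency values should not be compared with human
milliseconds, only the directional and interaction structure.
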
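# orthosim

Does the consistency of the first orthography you learn constrain how
well you can ever read a second one?  Bilingual naming experiments
suggest it does: readers whose first orthography is shallow (Italian-
like, near one-to-one letter-sound mappings) keep an advantage in
their first orthography that readers of a deep first orthography
(English-like, many-to-many and context-dependent) do not show, and
the asymmetry is clearest for pseudo-words, where only sublexical
decoding can operate.

`orthosim` implements the computational side of that question as a
tested R package: a two-layer linear associative network that learns
grapheme-to-phoneme decoding by the delta rule

&nbsp;&nbsp;&nbsp;&nbsp;ΔW = η (t − W x) xᵀ

over slot-coded disyllabic words, plus **cross-orthography weight
transfer** — a trained first-language (L1) network's weights are
copied, for every shared grapheme, onto every featurally close
second-language phoneme, and the resulting seeded network is trained
on the second orthography (L2).  Naming latency is read out as
deterministic cycles-to-threshold with competitive accumulation
(per-slot drift = winner net input − strongest competitor), so
mapping consistency → weight dilution → smaller margins → longer
latencies.  Artificial shallow/deep orthography generators, Zipfian
lexicons and pseudo-word construction make the whole pipeline
testable without any external data.

A second module implements the behavioural analysis pipeline of such
experiments: staged trial exclusion (voice key → accuracy → 3 SD) with
a conserving audit, log transform, per-subject first-orthography
advantage scores, pooled-t tests from printed group summaries, exact
small-sample rank tests, and random-intercept mixed models with the
planned difference-of-differences contrast (Satterthwaite-calibrated),
together with a calibrated trial-level RT generator.

## Worked example

```r
library(orthosim)

cfg <- experiment_config(record_curves = TRUE, seed = 1)
res <- run_experiment(cfg)

round(res$accuracies, 3)
#> L1_shallow    L1_deep L2_shallow    L2_deep
#>      1.000      0.975      1.000      1.000

presentations_to_criterion(res$curves$shallow)  # 500
presentations_to_criterion(res$curves$deep)     # 750

as.data.frame(res$contrasts)
#>   language lexicality mean_l1 mean_l2 difference        p
#> 1  shallow       word     101     101      0.150 1.17e-02
#> 2  shallow pseudoword     101     108      7.256 6.81e-12
#> 3     deep       word     134     126     -8.298 1.95e-02
#> 4     deep pseudoword     182     181     -0.839 8.28e-01

as.data.frame(res$weights)
#>        model used transferred overlap
#> 1 L1_shallow 2132           0   0.000
#> 2    L1_deep 4208           0   0.000
#> 3 L2_shallow 3114        7735   0.864
#> 4    L2_deep 4411        8464   0.801
```

Reading the output: the shallow orthography is learned to the 95%
word-accuracy criterion in 500 presentations against the deep
orthography's 750.  The L2-shallow network —
an English-first reader learning Italian second — is 7.3 cycles slower
than the native-shallow network on pseudo-words (rank-sum p ≈ 7e-12),
while the two deep-orthography networks do not differ reliably: the
deep-first reader cannot fully catch up with the shallow orthography's
simplicity, but a shallow-first reader loses nothing on the deep one.
The weight table shows why: the deep network *uses* about twice as
many weights (4208 vs 2132 above threshold), transfer writes a similar
number of entries in both directions (7735 vs 8464), and so the
proportion of used weights that transfer seeded is higher in the
shallow-after-deep network (0.864 vs 0.801) — the deep-first network
imports many associations the shallow orthography never uses, which
must be unlearned and still leak into novel strings.

The RT side in three lines:

```r
trials <- simulate_rt_dataset(rt_sim_config(seed = 11, emit_covariates = TRUE))
kept   <- exclude_trials(trials)$kept
fit    <- fit_rt_model(kept[kept$task == "blocked", ])
c(contrast = fit$contrast, p = fit$p)
#>     contrast            p
#> 1.596395e-01 3.984420e-24
```

The contrast is the planned comparison — how much bigger the
between-group RT difference is for Italian than for English stimuli,
in log-RT units — recovered here from a dataset whose effect sizes are
calibrated to the published word-reading cell means.

The numbered scripts under `analysis/` walk through the full study:
orthography construction (`01`), the four-model experiment (`02`), the
ten-seed robustness battery (`03`) and the behavioural pipeline
(`04`), each printing its findings and writing tables under
`results/`.

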
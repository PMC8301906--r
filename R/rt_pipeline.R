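#' Staged trial exclusion for naming-latency data
#'
#' Applies, in order: (1) removal of trials with invalid voice-key
#' triggers; (2) removal of inaccurate readings; (3) removal of trials
#' whose raw RT lies three or more standard deviations from the mean of
#' the remaining analysis set.  The stages are strictly ordered, so an
#' inaccurate trial with an extreme RT is counted at stage 2, never at
#' stage 3.
#'
#' @param trials tibble of trial records with columns `rt_ms`,
#'   `accurate`, `voice_key_valid` (and any others, carried through).
#' @param sd_cutoff outlier criterion in standard deviations (default 3).
#' @param per_cell if `TRUE`, the outlier stage is applied within each
#'   `language` x `task` x `lexicality` cell instead of over the whole
#'   analysis set.
#' @return list with `kept` (the retained trials) and `audit`, a tibble
#'   with one row per stage (`stage`, `removed`, `pct` of the input).
#'   Counts always satisfy `nrow(kept) + sum(removed) == nrow(trials)`.
#' @export
exclude_trials <- function(trials, sd_cutoff = 3, per_cell = FALSE) {
  if (nrow(trials) == 0L) stop("no trials to filter")
  n0 <- nrow(trials)
  s1 <- trials[trials$voice_key_valid, , drop = FALSE]
  s2 <- s1[s1$accurate, , drop = FALSE]
  if (nrow(s2) == 0L) stop("all trials removed before the outlier stage")
  extreme <- if (per_cell) {
    cell <- interaction(s2$language, s2$task, s2$lexicality, drop = TRUE)
    unsplit(lapply(split(s2$rt_ms, cell), function(x)
      abs(x - mean(x)) >= sd_cutoff * sd(x)), cell)
  } else {
    abs(s2$rt_ms - mean(s2$rt_ms)) >= sd_cutoff * sd(s2$rt_ms)
  }
  extreme[is.na(extreme)] <- FALSE
  kept <- s2[!extreme, , drop = FALSE]
  if (nrow(kept) == 0L) stop("all trials removed")
  audit <- tibble::tibble(
    stage = c("voice_key", "accuracy", "outlier"),
    removed = c(n0 - nrow(s1), nrow(s1) - nrow(s2), sum(extreme)),
    pct = 100 * c(n0 - nrow(s1), nrow(s1) - nrow(s2), sum(extreme)) / n0)
  list(kept = kept, audit = audit)
}

#' Log-transform reaction times
#'
#' Adds a natural-log `log_rt` column; the raw `rt_ms` column is
#' retained.
#'
#' @param trials trial tibble with positive `rt_ms`.
#' @return the tibble with a `log_rt` column.
#' @export
log_rt <- function(trials) {
  if (any(trials$rt_ms <= 0)) stop("non-positive reaction times")
  trials$log_rt <- log(trials$rt_ms)
  trials
}

#' Per-subject first-orthography advantage
#'
#' For each subject and task, the mean RT over accurate valid trials of
#' the second orthography minus that of the first orthography, where
#' the first orthography is determined by the subject's group (Italian
#' for L1-Italian bilinguals, English for L1-English bilinguals).
#' Positive values mean the first orthography is read faster.
#'
#' @param trials trial tibble with `subject_id`, `group`, `language`,
#'   `task`, `rt_ms`, `accurate`, `voice_key_valid`.
#' @return tibble `subject_id`, `group`, `task`, `o1_advantage`.
#'   Subjects missing one of the two language cells for a task are
#'   flagged in the `dropped` attribute and excluded.
#' @export
o1_advantage <- function(trials) {
  tr <- trials[trials$accurate & trials$voice_key_valid, , drop = FALSE]
  o1_of <- function(group) ifelse(group == "L1-Italian", "Italian", "English")
  key <- unique(tr[, c("subject_id", "group", "task")])
  rows <- vector("list", nrow(key))
  dropped <- character(0)
  for (i in seq_len(nrow(key))) {
    sel <- tr$subject_id == key$subject_id[i] & tr$task == key$task[i]
    o1 <- tr$rt_ms[sel & tr$language == o1_of(key$group[i])]
    o2 <- tr$rt_ms[sel & tr$language != o1_of(key$group[i])]
    if (length(o1) == 0L || length(o2) == 0L) {
      dropped <- c(dropped,
                   paste(key$subject_id[i], key$task[i], sep = "/"))
      next
    }
    rows[[i]] <- tibble::tibble(
      subject_id = key$subject_id[i], group = key$group[i],
      task = key$task[i], o1_advantage = mean(o2) - mean(o1))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  attr(out, "dropped") <- dropped
  out
}

#' Two-sample t test from printed group summaries
#'
#' Pooled-variance (Student) two-sample t test computed from means,
#' standard deviations and group sizes alone, as needed to check the
#' group comparisons that demographic tables report; `df = n_a + n_b -
#' 2` and the p value is two-tailed.
#'
#' @param a,b group summaries: lists or named vectors with elements
#'   `mean`, `sd`, `n` (n >= 2, sd >= 0).
#' @return list with `t`, `df`, `p`.  Zero pooled variance with unequal
#'   means yields an infinite t with a warning.
#' @export
t_from_summary <- function(a, b) {
  a <- as.list(a); b <- as.list(b)
  stopifnot(a$n >= 2, b$n >= 2, a$sd >= 0, b$sd >= 0)
  df <- a$n + b$n - 2
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
  se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  if (se == 0) {
    if (a$mean == b$mean) return(list(t = 0, df = df, p = 1))
    warning("zero pooled variance with unequal means; t is infinite")
    return(list(t = sign(a$mean - b$mean) * Inf, df = df, p = 0))
  }
  t <- (a$mean - b$mean) / se
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Rank-based two-sample or paired comparison
#'
#' Mann-Whitney rank-sum test for independent samples and Wilcoxon
#' signed-rank test for paired data, with the exact small-sample null
#' distribution when both samples have at most `exact_max` observations
#' and no ties, and the normal approximation otherwise.
#'
#' @param x,y numeric samples (n >= 3 each; equal length when paired).
#' @param paired use the signed-rank test on `x - y`.
#' @param exact_max largest per-sample size for which the exact
#'   distribution is used (default 12).
#' @return list with `statistic` (named `W` or `V`), `p`, and `method`.
#' @export
rank_tests <- function(x, y, paired = FALSE, exact_max = 12) {
  stopifnot(length(x) >= 3, length(y) >= 3)
  if (length(unique(c(x, y))) == 1L) stop("all observations are tied")
  exact <- length(x) <= exact_max && length(y) <= exact_max
  res <- suppressWarnings(
    wilcox.test(x, y, paired = paired, exact = exact, correct = !exact))
  list(statistic = res$statistic, p = res$p.value,
       method = if (paired) "Wilcoxon signed rank (V)"
                else "Mann-Whitney rank sum (W)")
}
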
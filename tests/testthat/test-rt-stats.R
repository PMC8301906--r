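clean_trials <- function(n = 1000, seed = 60) {
  set.seed(seed)
  tibble::tibble(
    subject_id = rep(sprintf("s%02d", 1:20), each = n / 20),
    group = rep(c("L1-Italian", "L1-English"), each = n / 2),
    language = rep(c("Italian", "English"), times = n / 2),
    task = "blocked", lexicality = "word",
    stimulus_id = sprintf("i%03d", rep(seq_len(n / 20), 20)),
    rt_ms = exp(log(600) + 0.1 * pmax(pmin(rnorm(n), 2.5), -2.5)),
    accurate = TRUE, voice_key_valid = TRUE)
}

test_that("a clean dataset passes exclusion untouched with an all-zero audit", {
  tr <- clean_trials()
  ex <- exclude_trials(tr)
  expect_equal(nrow(ex$kept), nrow(tr))
  expect_equal(ex$audit$removed, c(0, 0, 0))
  expect_equal(ex$audit$pct, c(0, 0, 0))
})

test_that("an injected extreme trial is removed at the outlier stage only", {
  tr <- clean_trials()
  m <- mean(tr$rt_ms); s <- sd(tr$rt_ms)
  spike <- tr[1, ]
  spike$rt_ms <- m + 5 * s
  spike$subject_id <- "s99"
  tr2 <- rbind(tr, spike)
  ex <- exclude_trials(tr2)
  expect_equal(ex$audit$removed, c(0, 0, 1))
  expect_false("s99" %in% ex$kept$subject_id)
  # brute-force recomputation of the 3-SD rule on the accuracy-filtered set
  keep_manual <- abs(tr2$rt_ms - mean(tr2$rt_ms)) < 3 * sd(tr2$rt_ms)
  expect_equal(sort(ex$kept$rt_ms), sort(tr2$rt_ms[keep_manual]))
})

test_that("stage order matters: an inaccurate extreme trial counts at stage 2", {
  tr <- clean_trials()
  spike <- tr[1, ]
  spike$rt_ms <- mean(tr$rt_ms) + 8 * sd(tr$rt_ms)
  spike$accurate <- FALSE
  ex <- exclude_trials(rbind(tr, spike))
  expect_equal(ex$audit$removed, c(0, 1, 0))

  bad_vk <- spike
  bad_vk$accurate <- TRUE
  bad_vk$voice_key_valid <- FALSE
  ex2 <- exclude_trials(rbind(tr, bad_vk))
  expect_equal(ex2$audit$removed, c(1, 0, 0))
})

test_that("audit counts always conserve the input trial total", {
  for (seed in 1:5) {
    cfg <- rt_sim_config(n_subjects_per_group = 6, n_items_per_cell = 8,
                         voice_key_fail_rate = 0.1, inaccuracy_rate = 0.05,
                         seed = seed)
    tr <- simulate_rt_dataset(cfg)
    for (per_cell in c(FALSE, TRUE)) {
      ex <- exclude_trials(tr, per_cell = per_cell)
      expect_equal(nrow(ex$kept) + sum(ex$audit$removed), nrow(tr))
    }
  }
  expect_error(exclude_trials(clean_trials()[0, ]), "no trials")
})

test_that("log transform is the natural log and keeps the raw column", {
  tr <- clean_trials(n = 100)
  tr$rt_ms[1] <- 1
  lt <- log_rt(tr)
  expect_equal(lt$log_rt[1], 0)
  expect_equal(exp(lt$log_rt), lt$rt_ms, tolerance = 1e-12)
  expect_equal(order(lt$log_rt), order(lt$rt_ms))
  tr$rt_ms[2] <- -1
  expect_error(log_rt(tr), "positive")
})

test_that("O1 advantage is group-relative and arithmetically exact", {
  tr <- tibble::tibble(
    subject_id = rep(c("a", "b"), each = 4),
    group = rep(c("L1-Italian", "L1-English"), each = 4),
    language = rep(c("Italian", "Italian", "English", "English"), 2),
    task = "blocked",
    rt_ms = c(600, 600, 650, 650,     # L1-Italian: O1 = Italian -> +50
              600, 600, 650, 650),    # L1-English: O1 = English -> -50
    accurate = TRUE, voice_key_valid = TRUE)
  adv <- o1_advantage(tr)
  expect_equal(adv$o1_advantage[adv$subject_id == "a"], 50)
  expect_equal(adv$o1_advantage[adv$subject_id == "b"], -50)

  # identical means give a zero advantage
  tr0 <- tr
  tr0$rt_ms <- 600
  expect_true(all(o1_advantage(tr0)$o1_advantage == 0))

  # a subject missing one language cell is flagged and dropped
  tr_miss <- tr[-(1:2), ]
  adv2 <- o1_advantage(tr_miss)
  expect_false("a" %in% adv2$subject_id)
  expect_match(attr(adv2, "dropped"), "a/blocked")
})

test_that("summary t tests reproduce direct computation and handle degenerate input", {
  # toy vectors: summary-based t equals t.test on the raw data
  x <- c(5.1, 4.9, 6.2, 5.8, 5.5)
  y <- c(4.2, 4.8, 4.4, 5.0, 4.1)
  res <- t_from_summary(list(mean = mean(x), sd = sd(x), n = length(x)),
                        list(mean = mean(y), sd = sd(y), n = length(y)))
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$df, unname(ref$parameter))
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)

  eq <- t_from_summary(c(mean = 5, sd = 1, n = 10), c(mean = 5, sd = 1, n = 10))
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)

  expect_warning(
    inf <- t_from_summary(c(mean = 5, sd = 0, n = 10),
                          c(mean = 4, sd = 0, n = 10)),
    "infinite")
  expect_equal(inf$t, Inf)
})

test_that("rank tests use the exact distribution for small samples", {
  # fully separated 5 vs 5: exact two-tailed p = 2/choose(10, 5)
  r <- rank_tests(1:5, 6:10)
  expect_equal(r$p, 2 / 252, tolerance = 1e-12)
  expect_equal(unname(r$statistic), 0)

  # identical samples: p essentially 1
  r2 <- rank_tests(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gte(r2$p, 0.99)

  expect_error(rank_tests(rep(1, 5), rep(1, 5)), "tied")

  # agreement with full enumeration on random small samples
  set.seed(61)
  for (rep in 1:10) {
    x <- round(rnorm(sample(4:6, 1)), 3)
    y <- round(rnorm(sample(4:6, 1)) + 0.5, 3)
    expect_equal(rank_tests(x, y)$p, mw_exact_oracle(x, y), tolerance = 1e-10)
  }

  # paired symmetric null: V centred on n(n+1)/4
  set.seed(62)
  vs <- replicate(200, {
    d <- rnorm(10)
    unname(rank_tests(d + 1:10, as.numeric(1:10), paired = TRUE)$statistic)
  })
  expect_equal(mean(vs), 10 * 11 / 4, tolerance = 0.15 * 10 * 11 / 4)
})
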
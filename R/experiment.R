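#' Configuration of the four-model transfer experiment
#'
#' Defines the synthetic language pair (one shallow and one deep
#' orthography over a shared grapheme inventory with counterpart
#' phonemes), the training budgets, the transfer rule and the latency
#' readout.  Defaults follow the simulated study conditions: 20
#' graphemes, depth 0.6, 500-word Zipfian lexicons, 300,000
#' first-language presentations, and asymmetric second-language budgets
#' (the deep-as-L2 network is trained twice as long as the
#' shallow-as-L2 network, 300,000 vs 150,000 presentations, reflecting
#' the assumption that reaching proficiency in the inconsistent
#' orthography takes longer).
#'
#' @param n_graphemes,depth_level,feature_len language-pair settings,
#'   see [build_language_pair()].
#' @param n_words,zipf_exponent lexicon settings per language.
#' @param eta_l1,eta_l2 learning rates; the second-language phase uses a
#'   smaller rate.
#' @param dead_band error-gating threshold of the learning rule used in
#'   all training phases (see [train_config()]): units already within
#'   this tolerance of their target are left alone, so learning stops
#'   refining what is already read well enough.
#' @param n_presentations_l1 first-language training budget.
#' @param n_presentations_l2_shallow,n_presentations_l2_deep
#'   second-language budgets by target orthography.
#' @param matched_training if `TRUE`, both second-language networks are
#'   trained with the first-language budget (the sensitivity analysis in
#'   which training amount is equated).
#' @param tau,scale transfer rule, see [transfer_config()].
#' @param latency a [latency_params()].
#' @param n_test_words,n_test_pseudo stimulus-set sizes per language.
#' @param theta_w absolute-weight threshold above which an entry counts
#'   as "used".
#' @param record_curves if `TRUE`, first-language training records word
#'   accuracy along a checkpoint grid that is dense (every `curve_every`
#'   presentations) up to 20 x `curve_every` and coarser afterwards.
#' @param curve_every base checkpoint interval for learning curves.
#' @param seed master seed; every random component derives from it.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(n_graphemes = 20, depth_level = 0.6,
                              feature_len = 8, n_words = 100,
                              zipf_exponent = 1,
                              eta_l1 = 0.05, eta_l2 = 0.01,
                              dead_band = 0,
                              n_presentations_l1 = 300000,
                              n_presentations_l2_shallow = 150000,
                              n_presentations_l2_deep = 300000,
                              matched_training = FALSE,
                              tau = 0, scale = 1,
                              latency = latency_params(),
                              n_test_words = 40, n_test_pseudo = 40,
                              theta_w = 0.01,
                              record_curves = FALSE, curve_every = 250,
                              seed = 1) {
  stopifnot(theta_w > 0)
  structure(as.list(environment()), class = "experiment_config")
}

#' Run the four-model sequential-learning experiment
#'
#' Trains first-language networks on the shallow and on the deep
#' orthography, seeds the two second-language networks by weight
#' transfer (shallow-after-deep and deep-after-shallow), trains them,
#' and tests each network on the blocked word and pseudo-word stimuli
#' of its own orthography (second-language networks only see their
#' second orthography, which is the only presentation mode the model
#' supports).  Weight-usage statistics and first- versus second-language
#' latency contrasts are computed per orthography.
#'
#' @param cfg an [experiment_config()].
#' @return list of class `ortho_experiment` with elements `items`
#'   (per model x stimulus readings), `weights` (used/transferred
#'   counts and overlap proportions), `contrasts` (latency contrasts
#'   per language x lexicality), `curves` (learning curves if
#'   recorded), `accuracies`, and `config`.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  set.seed(cfg$seed)
  sub <- sample.int(.Machine$integer.max %/% 2L, 12L)
  template <- slot_template()
  pair <- build_language_pair(cfg$n_graphemes, cfg$depth_level,
                              cfg$feature_len, seed = sub[1L])
  lex <- list(
    shallow = generate_lexicon(pair$shallow,
                               corpus_config(cfg$n_words, cfg$zipf_exponent,
                                             seed = sub[2L]), template),
    deep = generate_lexicon(pair$deep,
                            corpus_config(cfg$n_words, cfg$zipf_exponent,
                                          seed = sub[3L]), template))
  stim <- list(
    shallow = rbind(
      sample_word_stimuli(lex$shallow, pair$shallow, cfg$n_test_words,
                          seed = sub[4L]),
      generate_pseudowords(lex$shallow, pair$shallow, cfg$n_test_pseudo,
                           seed = sub[5L])),
    deep = rbind(
      sample_word_stimuli(lex$deep, pair$deep, cfg$n_test_words,
                          seed = sub[6L]),
      generate_pseudowords(lex$deep, pair$deep, cfg$n_test_pseudo,
                           seed = sub[7L])))

  curve_every <- if (cfg$record_curves)
    unique(c(seq(0L, 20L * cfg$curve_every, by = cfg$curve_every),
             seq(0L, cfg$n_presentations_l1, by = 40L * cfg$curve_every)))
  else NULL
  l2_budget <- function(lang) {
    if (cfg$matched_training) cfg$n_presentations_l1
    else if (lang == "shallow") cfg$n_presentations_l2_shallow
    else cfg$n_presentations_l2_deep
  }

  stage <- function(label, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", label, conditionMessage(e)), call. = FALSE))
  }
  nets <- list()
  tcfg <- function(eta, n, seed)
    train_config(eta, n, dead_band = cfg$dead_band, seed = seed)
  nets$L1_shallow <- stage("train L1 shallow",
    train(init_network(template, pair$shallow), lex$shallow,
          tcfg(cfg$eta_l1, cfg$n_presentations_l1, sub[8L]),
          pair$shallow, eval_every = curve_every, params = cfg$latency))
  nets$L1_deep <- stage("train L1 deep",
    train(init_network(template, pair$deep), lex$deep,
          tcfg(cfg$eta_l1, cfg$n_presentations_l1, sub[9L]),
          pair$deep, eval_every = curve_every, params = cfg$latency))
  tc <- transfer_config(cfg$tau, cfg$scale)
  seed_shallow <- stage("transfer deep -> shallow",
    transfer_weights(nets$L1_deep, pair$deep, pair$shallow, tc))
  seed_deep <- stage("transfer shallow -> deep",
    transfer_weights(nets$L1_shallow, pair$shallow, pair$deep, tc))
  nets$L2_shallow <- stage("train L2 shallow",
    train(seed_shallow, lex$shallow,
          tcfg(cfg$eta_l2, l2_budget("shallow"), sub[10L]), pair$shallow))
  nets$L2_deep <- stage("train L2 deep",
    train(seed_deep, lex$deep,
          tcfg(cfg$eta_l2, l2_budget("deep"), sub[11L]), pair$deep))

  model_language <- c(L1_shallow = "shallow", L1_deep = "deep",
                      L2_shallow = "shallow", L2_deep = "deep")
  items <- do.call(rbind, lapply(names(nets), function(m) {
    lang <- model_language[[m]]
    r <- batch_read(nets[[m]], stim[[lang]], cfg$latency, pair[[lang]])
    tibble::tibble(model = m, language = lang, spelling = r$spelling,
                   lexicality = r$lexicality, latency = r$latency,
                   correct = r$correct, margin = r$margin)
  }))

  weights <- do.call(rbind, lapply(names(nets), function(m)
    tibble::tibble(
      model = m,
      used = used_weights(nets[[m]], cfg$theta_w),
      transferred = count_transferred(nets[[m]]),
      overlap = transfer_overlap_proportion(nets[[m]], cfg$theta_w))))

  contrasts <- do.call(rbind, lapply(c("shallow", "deep"), function(lang)
    do.call(rbind, lapply(c("word", "pseudoword"), function(lx) {
      ct <- tryCatch(latency_contrast(items, lang, lx),
                     error = function(e) NULL)
      if (is.null(ct)) return(NULL)
      tibble::tibble(language = lang, lexicality = lx,
                     mean_l1 = ct$mean_l1, mean_l2 = ct$mean_l2,
                     difference = ct$difference, p = ct$p)
    }))))

  curves <- if (cfg$record_curves)
    list(shallow = attr(nets$L1_shallow, "curve"),
         deep = attr(nets$L1_deep, "curve"))
  accuracies <- vapply(names(nets), function(m) {
    sub_it <- items[items$model == m & items$lexicality == "word", ]
    mean(sub_it$correct)
  }, numeric(1))

  structure(list(items = items, weights = weights, contrasts = contrasts,
                 curves = curves, accuracies = accuracies, config = cfg,
                 networks = nets),
            class = "ortho_experiment")
}

#' Count weights in use
#'
#' @param net a `weight_matrix`.
#' @param theta_w positive absolute-weight threshold.
#' @return number of entries with `|w| > theta_w`.
#' @export
used_weights <- function(net, theta_w) {
  stopifnot(theta_w > 0)
  sum(abs(net$W) > theta_w)
}

#' Proportion of used weights that were seeded by transfer
#'
#' @inheritParams used_weights
#' @return `|used & transferred| / |used|`, or 0 when no entry is in
#'   use (first-language networks score 0 because their mask is empty).
#' @export
transfer_overlap_proportion <- function(net, theta_w) {
  used <- abs(net$W) > theta_w
  n_used <- sum(used)
  if (n_used == 0L) return(0)
  sum(used & net$mask) / n_used
}

#' First- versus second-language latency contrast
#'
#' Rank-based two-sample comparison (Wilcoxon rank-sum) of
#' correct-trial latencies between the first- and second-language model
#' of one orthography.  Positive differences mean the second-language
#' model is slower.
#'
#' @param items `items` table of an [run_experiment()] result.
#' @param language `"shallow"` or `"deep"`.
#' @param lexicality `"word"` or `"pseudoword"`.
#' @return list: `mean_l1`, `mean_l2`, `difference` (L2 minus L1), `p`.
#' @export
latency_contrast <- function(items, language, lexicality) {
  sel <- items$language == language & items$lexicality == lexicality
  l1 <- items$latency[sel & items$model == paste0("L1_", language) &
                        items$correct]
  l2 <- items$latency[sel & items$model == paste0("L2_", language) &
                        items$correct]
  if (length(l1) < 2L || length(l2) < 2L)
    stop("fewer than 2 correct items in one of the models")
  p <- if (all(l1 == l1[1L]) && all(l2 == l2[1L]) && l1[1L] == l2[1L]) 1
  else suppressWarnings(wilcox.test(l2, l1)$p.value)
  list(mean_l1 = mean(l1), mean_l2 = mean(l2),
       difference = mean(l2) - mean(l1), p = p)
}

#' Presentations needed to reach an accuracy criterion
#'
#' @param curve learning-curve tibble (`presentations`, `accuracy`).
#' @param criterion accuracy criterion (default 0.95).
#' @return smallest checkpoint at which accuracy first reaches the
#'   criterion, or `Inf` if it never does.
#' @export
presentations_to_criterion <- function(curve, criterion = 0.95) {
  hit <- which(curve$accuracy >= criterion)
  if (length(hit) == 0L) return(Inf)
  curve$presentations[hit[1L]]
}

#' Run the headline experiment over several master seeds
#'
#' Repeats [run_experiment()] (with learning curves) for a grid of
#' master seeds and collects the quantities that carry the study's
#' directional claims: presentations-to-criterion for each
#' first-language model, the first- versus second-language pseudo-word
#' latency contrasts per orthography, and the weight-usage statistics.
#'
#' @param seeds integer vector of master seeds.
#' @param cfg base [experiment_config()]; its seed is replaced per run.
#' @param matched if `TRUE`, each seed is additionally run in
#'   matched-training mode and the matched pseudo-word and word
#'   contrasts of the shallow language are reported alongside.
#' @return tibble with one row per seed.
#' @export
run_seed_battery <- function(seeds, cfg = experiment_config(),
                             matched = TRUE) {
  do.call(rbind, lapply(seeds, function(s) {
    cfg$seed <- s
    cfg$record_curves <- TRUE
    res <- run_experiment(cfg)
    ctr <- res$contrasts
    pick <- function(lang, lx, col, tab = ctr) {
      v <- tab[[col]][tab$language == lang & tab$lexicality == lx]
      if (length(v) == 0L) NA_real_ else v
    }
    mt <- if (matched) {
      cfg_m <- cfg
      cfg_m$matched_training <- TRUE
      cfg_m$record_curves <- FALSE
      run_experiment(cfg_m)$contrasts
    }
    w <- res$weights
    tibble::tibble(
      seed = s,
      pres95_shallow = presentations_to_criterion(res$curves$shallow),
      pres95_deep = presentations_to_criterion(res$curves$deep),
      acc_l1_shallow = res$accuracies[["L1_shallow"]],
      acc_l1_deep = res$accuracies[["L1_deep"]],
      gap_pseudo_shallow = pick("shallow", "pseudoword", "difference"),
      p_pseudo_shallow = pick("shallow", "pseudoword", "p"),
      gap_pseudo_deep = pick("deep", "pseudoword", "difference"),
      p_pseudo_deep = pick("deep", "pseudoword", "p"),
      gap_word_shallow = pick("shallow", "word", "difference"),
      p_word_shallow = pick("shallow", "word", "p"),
      gap_pseudo_shallow_matched = if (matched)
        pick("shallow", "pseudoword", "difference", mt) else NA_real_,
      p_pseudo_shallow_matched = if (matched)
        pick("shallow", "pseudoword", "p", mt) else NA_real_,
      gap_word_shallow_matched = if (matched)
        pick("shallow", "word", "difference", mt) else NA_real_,
      p_word_shallow_matched = if (matched)
        pick("shallow", "word", "p", mt) else NA_real_,
      used_l1_shallow = w$used[w$model == "L1_shallow"],
      used_l1_deep = w$used[w$model == "L1_deep"],
      overlap_l2_shallow = w$overlap[w$model == "L2_shallow"],
      overlap_l2_deep = w$overlap[w$model == "L2_deep"],
      transferred_to_shallow = w$transferred[w$model == "L2_shallow"],
      transferred_to_deep = w$transferred[w$model == "L2_deep"])
  }))
}
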
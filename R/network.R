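#' Training settings for the decoding network
#'
#' @param eta delta-rule learning rate (> 0).
#' @param n_presentations number of single-word presentations (>= 0).
#' @param sampling_exponent exponent applied to the log-compressed
#'   frequency when sampling items: presentation probability is
#'   proportional to `log(1 + frequency)^sampling_exponent`.
#' @param dead_band error-gating threshold: output units whose absolute
#'   error is below this value are not updated on a presentation.  Keeps
#'   converged weight structure sparse (units already read correctly stop
#'   being adjusted); 0 gives the pure delta rule.
#' @param seed RNG seed for the presentation schedule.
#' @return object of class `train_config`.
#' @export
train_config <- function(eta = 0.05, n_presentations = 300000,
                         sampling_exponent = 1, dead_band = 0,
                         seed = 1) {
  stopifnot(eta > 0, n_presentations >= 0, dead_band >= 0)
  structure(list(eta = eta, n_presentations = as.integer(n_presentations),
                 sampling_exponent = sampling_exponent,
                 dead_band = dead_band, seed = as.integer(seed)),
            class = "train_config")
}

#' Naming-latency readout settings
#'
#' Latency is modelled as deterministic cycles-to-threshold with
#' competitive accumulation: each filled slot's winning phoneme unit
#' accumulates activation `c * step * drift` (clipped at `threshold`)
#' over cycles `c`, where the drift is the winner's net input minus
#' the strongest positive competing activation in the slot; the item's
#' latency is the first cycle at which every filled slot's winner has
#' reached threshold, capped at `max_cycles`.
#'
#' @param threshold activation criterion in (0, 1].
#' @param step accumulation step per cycle (> 0).
#' @param max_cycles latency cap; also reported when some slot never
#'   crosses threshold.
#' @return object of class `latency_params`.
#' @export
latency_params <- function(threshold = 1, step = 0.01, max_cycles = 200) {
  stopifnot(threshold > 0, threshold <= 1, step > 0, max_cycles >= 1)
  structure(list(threshold = threshold, step = step,
                 max_cycles = as.integer(max_cycles)),
            class = "latency_params")
}

#' Initialise an all-zero decoding network
#'
#' The network is a single real weight matrix from slot-coded grapheme
#' units to slot-coded phoneme units (linear activation), plus a boolean
#' mask marking entries written by cross-orthography transfer (all false
#' for a first-language network).
#'
#' @param template a [slot_template()].
#' @param table the [mapping_table()] whose inventories define the unit
#'   layout.
#' @return object of class `weight_matrix` with elements `W`, `mask`,
#'   `language_id`, `graphemes`, `phonemes`, `template`.
#' @export
init_network <- function(template, table) {
  g <- table$graphemes$grapheme
  p <- table$phonemes$symbol
  in_dim <- template$n_slots * (length(g) + 1L)
  out_dim <- template$n_slots * (length(p) + 1L)
  structure(
    list(W = matrix(0, out_dim, in_dim),
         mask = matrix(FALSE, out_dim, in_dim),
         language_id = table$language_id,
         graphemes = g, phonemes = p, template = template),
    class = "weight_matrix")
}

#' @exportS3Method base::print
print.weight_matrix <- function(x, ...) {
  cat(sprintf("<weight_matrix '%s'>: %d x %d, %d nonzero, %d transferred\n",
              x$language_id, nrow(x$W), ncol(x$W), sum(x$W != 0), sum(x$mask)))
  invisible(x)
}

#' One delta-rule update
#'
#' `W <- W + eta * (t - W x) x^T`.  With one-hot slot coding only the
#' active input columns change.
#'
#' @param net a [init_network()] object.
#' @param x input activation vector.
#' @param target target activation vector.
#' @param eta learning rate.
#' @return the updated network.
#' @export
train_step <- function(net, x, target, eta) {
  if (!all(is.finite(x)) || !all(is.finite(target)))
    stop("non-finite activations")
  stopifnot(length(x) == ncol(net$W), length(target) == nrow(net$W))
  act <- which(x != 0)
  o <- net$W[, act, drop = FALSE] %*% x[act]
  err <- eta * (target - as.vector(o))
  net$W[, act] <- net$W[, act, drop = FALSE] + outer(err, x[act])
  net
}

## Precompute the active input/output unit indices of every lexicon item.
encode_lexicon <- function(lexicon, table, template) {
  n <- nrow(lexicon)
  act_in <- matrix(0L, template$n_slots, n)
  act_out <- matrix(0L, template$n_slots, n)
  parsed <- vector("list", n)
  for (i in seq_len(n)) {
    pf <- assign_slots(lexicon$segmentation[[i]], template, table)
    parsed[[i]] <- pf
    act_in[, i] <- active_input_units(pf, table)
    act_out[, i] <- active_target_units(pf, lexicon$pronunciation[[i]], table)
  }
  list(act_in = act_in, act_out = act_out, parsed = parsed)
}

presentation_probs <- function(frequency, sampling_exponent) {
  w <- log1p(frequency)^sampling_exponent
  w / sum(w)
}

#' Train the network on a frequency-sampled lexicon
#'
#' Samples `n_presentations` items (probability proportional to
#' `log(1 + frequency)^sampling_exponent`) and applies one delta-rule
#' update per presentation.  Deterministic under the schedule seed.
#' When `eval_every` is given, word accuracy over `eval_stimuli` is
#' recorded at each checkpoint, yielding a learning curve.
#'
#' @param net network from [init_network()] (or a transferred one).
#' @param lexicon training lexicon from [generate_lexicon()].
#' @param cfg a [train_config()].
#' @param table the language's [mapping_table()].
#' @param eval_every checkpoint interval in presentations, a vector of
#'   checkpoint positions, or `NULL` for no curve.
#' @param eval_stimuli stimulus tibble for checkpoint accuracy (defaults
#'   to the whole lexicon read as words).
#' @param params [latency_params()] used for checkpoint accuracy.
#' @return the trained network; with checkpoints, the learning curve is
#'   attached as attribute `"curve"` (tibble `presentations`,
#'   `accuracy`).
#' @export
train <- function(net, lexicon, cfg, table, eval_every = NULL,
                  eval_stimuli = NULL, params = latency_params()) {
  enc <- encode_lexicon(lexicon, table, net$template)
  set.seed(cfg$seed)
  if (cfg$n_presentations == 0L) {
    if (is.null(eval_every)) return(net)
  }
  schedule <- if (cfg$n_presentations > 0L)
    sample.int(nrow(lexicon), cfg$n_presentations, replace = TRUE,
               prob = presentation_probs(lexicon$frequency,
                                         cfg$sampling_exponent))
  else integer(0)
  if (is.null(eval_every)) {
    net$W <- .delta_train_cpp(net$W, enc$act_in, enc$act_out, schedule,
                              cfg$eta, cfg$dead_band)
    return(net)
  }
  if (is.null(eval_stimuli))
    eval_stimuli <- tibble::tibble(
      spelling = lexicon$spelling, lexicality = "word",
      language_id = table$language_id, segmentation = lexicon$segmentation,
      acceptable = lapply(lexicon$pronunciation, list))
  breaks <- if (length(eval_every) == 1L)
    seq(0L, cfg$n_presentations, by = eval_every)
  else sort(eval_every[eval_every <= cfg$n_presentations])
  breaks <- unique(c(as.integer(breaks), cfg$n_presentations))
  if (breaks[1L] != 0L) breaks <- c(0L, breaks)
  curve <- data.frame(presentations = breaks, accuracy = NA_real_)
  curve$accuracy[1L] <- accuracy(net, eval_stimuli, params, table)
  for (b in seq_len(length(breaks) - 1L)) {
    chunk <- schedule[(breaks[b] + 1L):breaks[b + 1L]]
    net$W <- .delta_train_cpp(net$W, enc$act_in, enc$act_out, chunk,
                              cfg$eta, cfg$dead_band)
    curve$accuracy[b + 1L] <- accuracy(net, eval_stimuli, params, table)
  }
  attr(net, "curve") <- tibble::as_tibble(curve)
  net
}

#' Read a stimulus set in batch
#'
#' Computes, for every stimulus, the per-slot winning phoneme units of
#' the linear network, the cycles-to-threshold naming latency, the
#' decision margin (smallest winner-minus-runner-up net input over
#' filled slots), and correctness against the item's acceptable
#' pronunciations (slot-aligned).
#'
#' @param net trained [init_network()] object.
#' @param stimuli stimulus tibble (see [sample_word_stimuli()]).
#' @param params [latency_params()].
#' @param table the language's [mapping_table()].
#' @return tibble: `spelling`, `lexicality`, `latency`, `correct`,
#'   `margin`, `pronunciation` (list of winner symbols of filled slots).
#' @export
batch_read <- function(net, stimuli, params, table) {
  if (nrow(stimuli) == 0L) stop("empty stimulus set")
  template <- net$template
  n <- nrow(stimuli)
  inv_g <- length(net$graphemes)
  X <- matrix(0, ncol(net$W), n)
  parsed <- vector("list", n)
  for (i in seq_len(n)) {
    pf <- assign_slots(stimuli$segmentation[[i]], template, table)
    parsed[[i]] <- pf
    X[active_input_units(pf, table), i] <- 1
  }
  O <- net$W %*% X                      # out_dim x n net inputs
  blk <- length(net$phonemes) + 1L
  win_idx <- matrix(0L, template$n_slots, n)
  win_val <- matrix(0, template$n_slots, n)
  run_val <- matrix(0, template$n_slots, n)
  for (s in seq_len(template$n_slots)) {
    rows <- (s - 1L) * blk + seq_len(blk)
    block <- O[rows, , drop = FALSE]
    w <- max.col(t(block), ties.method = "first")
    win_idx[s, ] <- w
    win_val[s, ] <- block[cbind(w, seq_len(n))]
    block[cbind(w, seq_len(n))] <- -Inf
    run_val[s, ] <- apply(block, 2, max)
  }
  latency <- integer(n)
  correct <- logical(n)
  margin <- numeric(n)
  prons <- vector("list", n)
  for (i in seq_len(n)) {
    filled <- which(!is.na(parsed[[i]]$slots))
    v <- win_val[filled, i]
    margin[i] <- min(v - run_val[filled, i])
    ## competitive accumulation: per-slot drift is the winner's net input
    ## minus the strongest competing activation (if positive), so diluted
    ## or ambiguous mappings settle more slowly
    rate <- v - pmax(run_val[filled, i], 0)
    if (any(rate <= 0) || any(v <= 0)) {
      latency[i] <- params$max_cycles
    } else {
      latency[i] <- min(params$max_cycles,
                        max(ceiling(params$threshold / (params$step * rate))))
    }
    w <- win_idx[, i]
    winners <- ifelse(w == blk, NA_character_, net$phonemes[w])
    prons[[i]] <- winners[filled]
    aligned_ok <- any(vapply(stimuli$acceptable[[i]], function(pr)
      length(pr) == length(filled) && all(winners[filled] == pr) &&
        all(v > 0), logical(1)))
    empty_ok <- all(w[-filled] == blk | win_val[-filled, i] <= 0) ||
      length(filled) == template$n_slots
    correct[i] <- aligned_ok && empty_ok
  }
  tibble::tibble(spelling = stimuli$spelling,
                 lexicality = stimuli$lexicality,
                 latency = latency, correct = correct, margin = margin,
                 pronunciation = prons)
}

#' Read a single item aloud
#'
#' Single-item wrapper around [batch_read()].
#' @inheritParams batch_read
#' @param item one-row stimulus tibble.
#' @return list with `pronunciation`, `latency`, `correct`, `margin`.
#' @export
read_aloud <- function(net, item, params, table) {
  r <- batch_read(net, item[1L, ], params, table)
  list(pronunciation = r$pronunciation[[1L]], latency = r$latency[1L],
       correct = r$correct[1L], margin = r$margin[1L])
}

#' Proportion of correctly read stimuli
#'
#' @inheritParams batch_read
#' @return proportion in `[0, 1]`.
#' @export
accuracy <- function(net, stimuli, params, table) {
  mean(batch_read(net, stimuli, params, table)$correct)
}

#' Save and load a network checkpoint
#'
#' Plain-text JSON dump of the weight matrix, transfer mask and unit
#' layout; the round trip is lossless.
#'
#' @param net a `weight_matrix` object.
#' @param path file path.
#' @return `read_checkpoint()` returns the network; `write_checkpoint()`
#'   its path, invisibly.
#' @export
write_checkpoint <- function(net, path) {
  obj <- list(language_id = net$language_id,
              dim = dim(net$W),
              graphemes = net$graphemes, phonemes = net$phonemes,
              template = unclass(net$template)[c("n_syllables", "onset_slots",
                                                 "coda_slots")],
              W = as.vector(net$W),
              mask = which(net$mask))
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  template <- slot_template(obj$template$n_syllables, obj$template$onset_slots,
                            obj$template$coda_slots)
  W <- matrix(obj$W, obj$dim[1L], obj$dim[2L])
  mask <- matrix(FALSE, obj$dim[1L], obj$dim[2L])
  mask[obj$mask] <- TRUE
  structure(list(W = W, mask = mask, language_id = obj$language_id,
                 graphemes = obj$graphemes, phonemes = obj$phonemes,
                 template = template),
            class = "weight_matrix")
}
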
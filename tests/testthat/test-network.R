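test_that("initial networks are zero with the right geometry", {
  tab <- tiny_table()
  tpl <- slot_template()
  net <- init_network(tpl, tab)
  expect_equal(dim(net$W), c(tpl$n_slots * 7, tpl$n_slots * 7))
  expect_equal(sum(abs(net$W)), 0)
  expect_false(any(net$mask))

  # untrained network: latency = max_cycles, nothing read correctly
  stim <- words_as_stimuli(toy_lexicon(tab), tab)
  r <- batch_read(net, stim, latency_params(), tab)
  expect_true(all(r$latency == latency_params()$max_cycles))
  expect_true(all(!r$correct))
  expect_equal(accuracy(net, stim, latency_params(), tab), 0)
})

test_that("single delta-rule steps follow the closed form", {
  tab <- tiny_table()
  tpl <- slot_template()
  net <- init_network(tpl, tab)
  # a single grapheme-phoneme pair: one active input unit, one target unit
  x <- numeric(ncol(net$W)); x[3] <- 1
  target <- numeric(nrow(net$W)); target[3] <- 1

  net1 <- train_step(net, x, target, eta = 0.5)
  expect_equal(net1$W[3, 3], 0.5)                   # eta * (1 - 0)
  expect_equal(sum(net1$W != 0), 1)
  net2 <- train_step(net1, x, target, eta = 0.5)
  expect_equal(net2$W[3, 3], 0.75)                  # geometric approach to 1

  # an already-perfect mapping is left untouched
  net_perfect <- net
  net_perfect$W[3, 3] <- 1
  net3 <- train_step(net_perfect, x, target, eta = 0.5)
  expect_equal(net3$W, net_perfect$W)

  # the general multi-slot update matches W + eta (t - W x) x^T
  pf <- assign_slots(c("t", "a"), tpl, tab)
  xf <- encode(pf, tab)
  tf <- numeric(nrow(net$W))
  tf[orthosim:::active_target_units(pf, c("toy_p3", "toy_p1"), tab)] <- 1
  set.seed(36)
  net_r <- net
  net_r$W <- matrix(rnorm(length(net$W), sd = 0.05), nrow(net$W))
  stepped <- train_step(net_r, xf, tf, eta = 0.2)
  expect_equal(stepped$W,
               net_r$W + 0.2 * (tf - drop(net_r$W %*% xf)) %o% xf,
               tolerance = 1e-12)

  expect_error(train_step(net, x * NA, target, 0.1), "finite")
})

test_that("training converges to the least-squares solution on a consistent corpus", {
  skip_if_not_installed("MASS")
  tab <- tiny_table()
  tpl <- slot_template()
  lex <- toy_lexicon(tab)
  net0 <- init_network(tpl, tab)

  net <- train(net0, lex, train_config(eta = 0.05, n_presentations = 5000,
                                       seed = 30), tab)
  W_star <- ls_oracle(net0, lex, tab)

  # mean squared output error below 1e-3
  enc <- orthosim:::encode_lexicon(lex, tab, tpl)
  mse <- mean(vapply(seq_len(nrow(lex)), function(i) {
    o <- rowSums(net$W[, enc$act_in[, i]])
    t_ <- numeric(nrow(net$W)); t_[enc$act_out[, i]] <- 1
    mean((t_ - o)^2)
  }, numeric(1)))
  expect_lt(mse, 1e-3)

  # elementwise agreement with the pseudoinverse oracle
  expect_lt(max(abs(net$W - W_star)), 1e-2)

  # zero presentations change nothing
  net_same <- train(net0, lex, train_config(eta = 0.05, n_presentations = 0,
                                            seed = 31), tab)
  expect_equal(net_same$W, net0$W)
})

test_that("expected squared error is non-increasing over training", {
  tab <- tiny_table()
  tpl <- slot_template()
  lex <- toy_lexicon(tab)
  enc <- orthosim:::encode_lexicon(lex, tab, tpl)
  sse <- function(net) sum(vapply(seq_len(nrow(lex)), function(i) {
    o <- rowSums(net$W[, enc$act_in[, i]])
    t_ <- numeric(nrow(net$W)); t_[enc$act_out[, i]] <- 1
    sum((t_ - o)^2)
  }, numeric(1)))
  for (seed in 1:3) {
    net <- init_network(tpl, tab)
    errs <- numeric(6)
    for (k in 1:6) {
      net <- train(net, lex, train_config(eta = 0.05, n_presentations = 200,
                                          seed = seed * 10 + k), tab)
      errs[k] <- sse(net)
    }
    expect_true(all(diff(errs) < 1e-8))
  }
})

test_that("latency follows the cycles-to-threshold closed form", {
  tab <- tiny_table()
  tpl <- slot_template()
  net <- init_network(tpl, tab)
  lex <- toy_lexicon(tab)
  stim <- words_as_stimuli(lex, tab)[1, ]
  enc <- orthosim:::encode_lexicon(lex[1, ], tab, tpl)
  # net input exactly 1 on each filled slot's target, no competition
  net$W[cbind(enc$act_out[, 1], enc$act_in[, 1])] <- 1

  r <- read_aloud(net, stim, latency_params(threshold = 1, step = 0.1,
                                            max_cycles = 200), tab)
  expect_equal(r$latency, 10)                        # ceil(1 / (0.1 * 1))
  expect_true(r$correct)
  expect_equal(r$pronunciation, lex$pronunciation[[1]])

  # a zeroed (filled) slot never crosses threshold; slot 3 holds the onset
  net0 <- net
  net0$W[enc$act_out[3, 1], ] <- 0
  r0 <- read_aloud(net0, stim, latency_params(step = 0.1), tab)
  expect_equal(r0$latency, 200)
  expect_false(r0$correct)
})

test_that("latency is monotone in the winning net input", {
  tab <- tiny_table()
  tpl <- slot_template()
  lex <- toy_lexicon(tab)
  stim <- words_as_stimuli(lex, tab)[1, ]
  enc <- orthosim:::encode_lexicon(lex[1, ], tab, tpl)
  params <- latency_params(threshold = 1, step = 0.02, max_cycles = 500)
  brute_latency <- function(rates) {
    # smallest c with c * step * rate >= threshold for every slot
    for (c in seq_len(params$max_cycles)) {
      if (all(c * params$step * rates >= params$threshold)) return(c)
    }
    params$max_cycles
  }
  set.seed(33)
  for (rep in 1:20) {
    vals <- runif(ncol(enc$act_out), 0.2, 1.5)
    net <- init_network(tpl, tab)
    net$W[cbind(enc$act_out[, 1], enc$act_in[, 1])] <- vals[1]
    r1 <- read_aloud(net, stim, params, tab)
    expect_equal(r1$latency, brute_latency(rep(vals[1], 12)))
    # raising the winning input can only speed reading up
    net$W[cbind(enc$act_out[, 1], enc$act_in[, 1])] <- vals[1] * 1.5
    r2 <- read_aloud(net, stim, params, tab)
    expect_lte(r2$latency, r1$latency)
  }
})

test_that("competition slows reading: larger margins mean shorter latencies", {
  tab <- tiny_table()
  tpl <- slot_template()
  lex <- toy_lexicon(tab)
  stim <- words_as_stimuli(lex, tab)[1, ]
  enc <- orthosim:::encode_lexicon(lex[1, ], tab, tpl)
  net <- init_network(tpl, tab)
  net$W[cbind(enc$act_out[, 1], enc$act_in[, 1])] <- 1
  params <- latency_params(threshold = 1, step = 0.01)
  base <- read_aloud(net, stim, params, tab)
  # activate a competitor in one filled slot
  net$W[enc$act_out[3, 1] + 1L, enc$act_in[3, 1]] <- 0.5
  slowed <- read_aloud(net, stim, params, tab)
  expect_gt(slowed$latency, base$latency)
  expect_lt(slowed$margin, base$margin)
  expect_true(slowed$correct)
})

test_that("accuracy is order-invariant and perfect after convergence", {
  tab <- tiny_table()
  lex <- toy_lexicon(tab)
  net <- train(init_network(slot_template(), tab), lex,
               train_config(eta = 0.05, n_presentations = 5000, seed = 34),
               tab)
  stim <- words_as_stimuli(lex, tab)
  p <- latency_params()
  expect_equal(accuracy(net, stim, p, tab), 1)
  expect_equal(accuracy(net, stim[rev(seq_len(nrow(stim))), ], p, tab), 1)
  expect_error(batch_read(net, stim[0, ], p, tab), "empty")
})

test_that("checkpoints round-trip losslessly", {
  tab <- tiny_table()
  lex <- toy_lexicon(tab)
  net <- train(init_network(slot_template(), tab), lex,
               train_config(eta = 0.05, n_presentations = 500, seed = 35),
               tab)
  net$mask[1:5, 2:3] <- TRUE
  f <- tempfile(fileext = ".json")
  write_checkpoint(net, f)
  net2 <- read_checkpoint(f)
  expect_identical(net2$W, net$W)
  expect_identical(net2$mask, net$mask)
  expect_identical(net2$language_id, net$language_id)
  expect_identical(net2$graphemes, net$graphemes)
  expect_identical(net2$phonemes, net$phonemes)
  unlink(f)
})
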
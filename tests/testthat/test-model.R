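test_that("noam schedule matches its closed form and peaks at warmup", {
  sch <- training_schedule(base_lr = 4, warmup_steps = 8000,
                           max_steps = 200000)
  expect_equal(noam_lr(8000, sch, 384), 4 * 384^-0.5 * 8000^-0.5)
  ## warmup ramp is linear: lr(1)/lr(2) = 1/2
  expect_equal(noam_lr(1, sch, 384) / noam_lr(2, sch, 384), 0.5)
  sweep <- noam_lr(seq_len(5 * 8000), sch, 384)
  expect_equal(which.max(sweep), 8000)
  expect_error(noam_lr(0, sch, 384), ">= 1")
})

test_that("multi-task interleaving honours the weights exactly per cycle", {
  mk <- function(n) list(src = rep(list(c(6L, 7L)), n),
                         tgt = rep(list(c(6L, 7L)), n), n = n)
  mix <- multitask_mixture(list(enzr = mk(5), general = mk(50)),
                           weights = c(1L, 9L))
  sched <- sample_multitask_batches(mix, 100)
  for (i in seq(1, 91, by = 10)) {
    expect_equal(sum(sched[i:(i + 9)] == "enzr"), 1)
  }
  ## 1:1 weights alternate strictly
  mix2 <- multitask_mixture(list(a = mk(3), b = mk(3)), weights = c(1L, 1L))
  expect_identical(sample_multitask_batches(mix2, 6),
                   rep(c("a", "b"), 3))
  expect_error(multitask_mixture(list(a = mk(3), b = mk(3)), c(0L, 1L)),
               ">= 1")
})

test_that("every example in a corpus epoch is visited before any repeat", {
  set.seed(1)
  src <- lapply(1:37, function(i) sample(6:20, 8, replace = TRUE))
  enc <- list(src = src, tgt = src, n = 37)
  stream <- enzrxn:::batch_stream(enc, batch_tokens = 170)
  seen <- integer(0)
  repeat {
    b <- stream$next_batch()
    ids <- vapply(seq_len(b$B), function(i) {
      paste(b$src[((i - 1) * b$Ls + 1):(i * b$Ls)], collapse = ",")
    }, character(1))
    seen <- c(seen, match(ids, vapply(src, function(s) {
      paste(c(s, rep(1L, b$Ls - length(s))), collapse = ",")
    }, character(1))))
    if (length(seen) >= 37) break
  }
  expect_setequal(seen[1:37], 1:37)
})

test_that("analytic gradients match finite differences", {
  cfg <- model_config(layers = 1, model_dim = 8, heads = 2, ff_dim = 16,
                      dropout = 0, max_len = 16)
  m <- init_transformer(cfg, vocab_size = 11, seed = 3)
  b <- enzrxn:::make_batch(list(c(6L, 7L, 8L), c(9L, 10L, 6L, 7L)),
                           list(c(6L, 7L, 8L), c(9L, 10L, 6L)))
  ## the double-precision reference path is the differentiable oracle
  r <- enzrxn:::transformer_fb(m, b, grads = TRUE, train = FALSE,
                               engine = "r")
  eps <- 1e-6
  set.seed(42)
  for (nm in names(m$params)) {
    p <- m$params[[nm]]
    for (i in sample(length(p), min(3, length(p)))) {
      m2 <- m
      m2$params[[nm]][i] <- p[i] + eps
      up <- enzrxn:::transformer_fb(m2, b, grads = FALSE, train = FALSE,
                                    engine = "r")$loss
      m2$params[[nm]][i] <- p[i] - eps
      dn <- enzrxn:::transformer_fb(m2, b, grads = FALSE, train = FALSE,
                                    engine = "r")$loss
      num <- (up - dn) / (2 * eps)
      expect_equal(r$grads[[nm]][i], num, tolerance = 1e-4,
                   label = paste("grad", nm, i))
    }
  }
  ## and the compiled single-precision engine reproduces it
  rc <- enzrxn:::transformer_fb(m, b, grads = TRUE, train = FALSE,
                                engine = "cpp")
  expect_equal(rc$loss, r$loss, tolerance = 1e-5)
  for (nm in names(r$grads)) {
    expect_equal(rc$grads[[nm]], r$grads[[nm]], tolerance = 1e-3,
                 ignore_attr = TRUE, label = paste("cpp grad", nm))
  }
})

test_that("a small transformer masters a copy task", {
  set.seed(7)
  mk <- function(n) lapply(seq_len(n), function(i) {
    sample(6:15, sample(4L:8L, 1), replace = TRUE)
  })
  src <- mk(400)
  enc <- list(src = src, tgt = src, n = 400)
  vl <- mk(64)
  venc <- list(src = vl, tgt = vl, n = 64)
  cfg <- model_config(layers = 2, model_dim = 64, heads = 4, ff_dim = 128,
                      dropout = 0, max_len = 32)
  sch <- training_schedule(base_lr = 1.5, warmup_steps = 120, max_steps = 650,
                           batch_tokens = 512, seed = 11, valid_every = 650,
                           patience = 5)
  fit <- train_transformer(cfg, sch, enc, "single", valid = venc,
                           vocab_size = 16, quiet = TRUE)
  expect_gte(tail(fit$val_history$acc, 1), 0.99)
  ## loss trends downward
  h <- fit$history$loss
  expect_lt(mean(tail(h, 50)), mean(head(h, 50)) / 4)
})

test_that("training is deterministic for a fixed seed", {
  set.seed(1)
  src <- lapply(1:60, function(i) sample(6:15, 6, replace = TRUE))
  enc <- list(src = src, tgt = src, n = 60)
  cfg <- model_config(layers = 1, model_dim = 16, heads = 2, ff_dim = 32,
                      dropout = 0.1, max_len = 16)
  sch <- training_schedule(warmup_steps = 10, max_steps = 30,
                           batch_tokens = 256, seed = 5, valid_every = 0)
  f1 <- train_transformer(cfg, sch, enc, "single", vocab_size = 16,
                          quiet = TRUE)
  f2 <- train_transformer(cfg, sch, enc, "single", vocab_size = 16,
                          quiet = TRUE)
  expect_identical(f1$history$loss, f2$history$loss)
  expect_identical(f1$model$params$Wout, f2$model$params$Wout)
})

test_that("sequential transfer starts phase 2 below a cold start", {
  ## general task: copy; specialized task: copy of a disjoint id range whose
  ## token statistics still overlap in the embedding space
  set.seed(3)
  gsrc <- lapply(1:300, function(i) sample(6:12, 6, replace = TRUE))
  ssrc <- lapply(1:120, function(i) sample(8:14, 6, replace = TRUE))
  gen <- list(src = gsrc, tgt = gsrc, n = 300)
  spec <- list(src = ssrc, tgt = ssrc, n = 120)
  cfg <- model_config(layers = 1, model_dim = 32, heads = 2, ff_dim = 64,
                      dropout = 0, max_len = 16)
  sch <- training_schedule(base_lr = 1.5, warmup_steps = 60, max_steps = 150,
                           batch_tokens = 384, seed = 2, valid_every = 0)
  stl <- train_transformer(cfg, sch, list(general = gen, specialized = spec),
                           "stl", vocab_size = 15, quiet = TRUE)
  cold <- train_transformer(cfg, sch, spec, "single", vocab_size = 15,
                            quiet = TRUE)
  ph2 <- stl$history[stl$history$phase == "specialized", ]
  expect_lt(mean(head(ph2$loss, 5)), mean(head(cold$history$loss, 5)))
})

test_that("beam search agrees exactly with brute-force enumeration", {
  V <- 5L
  fn <- toy_step_fn(V)
  truth <- enumerate_best(fn, V, max_len = 3)
  ## width covering every possible partial sequence makes beam exhaustive
  got <- beam_search(fn, V, beam_width = 30L, n_best = 2L, max_len = 3)
  expect_identical(got$tokens[[1]], truth$ids[[1]])
  expect_equal(got$log_prob[1], truth$lp[1])
  expect_equal(got$log_prob[2], truth$lp[2])
  expect_equal(got$confidence, exp(got$log_prob))
  expect_error(beam_search(fn, V, beam_width = 2, n_best = 3), "n_best")
})

test_that("confidence is the product of token probabilities", {
  ## scorer emitting fixed probabilities (0.99, 0.99, then EOS with 1.0)
  fn <- function(prefixes) {
    t(vapply(prefixes, function(ids) {
      if (length(ids) <= 2) log(c(1e-12, 1e-12, 0.01, 0.99, 1e-12))
      else log(c(1e-12, 1e-12, 1 - 3e-12, 1e-12, 1e-12))
    }, numeric(5)))
  }
  got <- beam_search(fn, 5L, beam_width = 1L, n_best = 1L, max_len = 5)
  expect_equal(got$confidence[1], 0.9801, tolerance = 1e-6)
  expect_identical(got$tokens[[1]], c(4L, 4L))
})

test_that("the batched incremental decoder matches the training forward pass", {
  ## train a tiny model briefly, then check that greedy decoding with the
  ## cached decoder reproduces the argmax path of the full forward pass
  set.seed(9)
  src <- lapply(1:150, function(i) sample(6:14, sample(4:7, 1), replace = TRUE))
  tgt <- lapply(src, rev)
  enc <- list(src = src, tgt = tgt, n = 150)
  cfg <- model_config(layers = 2, model_dim = 32, heads = 4, ff_dim = 64,
                      dropout = 0, max_len = 24)
  sch <- training_schedule(base_lr = 0.8, warmup_steps = 80, max_steps = 450,
                           batch_tokens = 384, seed = 3, valid_every = 0)
  fit <- train_transformer(cfg, sch, enc, "single", vocab_size = 15,
                           quiet = TRUE)
  model <- fit$model
  dec <- decode_transformer(model, src[1:12], beam_width = 1L, n_best = 1L,
                            max_len = 12L)
  checked <- 0
  for (i in 1:12) {
    ids <- dec$ids[dec$source_index == i][[1]]
    ## only hypotheses that terminated with EOS carry the EOS log-prob term;
    ## force-finished ones (length == max_len) are skipped
    if (length(ids) >= 12) next
    ## teacher-force the decoded sequence: every step's argmax must be the
    ## decoded token (greedy self-consistency), and the log-prob must match
    ## (both paths in double precision)
    b <- enzrxn:::make_batch(src[i], list(ids))
    r <- enzrxn:::transformer_fb(model, b, grads = FALSE, train = FALSE,
                                 engine = "r")
    expect_gte(r$acc, 1)
    lp_full <- -r$loss * r$n_tokens
    expect_equal(dec$log_prob[dec$source_index == i][1], lp_full,
                 tolerance = 1e-7)
    checked <- checked + 1
  }
  expect_gte(checked, 8)
})
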
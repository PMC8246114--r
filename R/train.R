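## Training regimes: single-corpus, weighted multi-task (MTL) and sequential
## transfer learning (STL), with token-budget batching, noam-scheduled Adam,
## periodic teacher-forced validation and accuracy-based early stopping.

## Token-budget batching with length bucketing: shuffle, pool, sort each pool
## by source length, then pack consecutive sequences while the padded
## (src+tgt) token count stays within budget.
plan_batches <- function(src_lens, tgt_lens, batch_tokens, pool = 1024L) {
  n <- length(src_lens)
  idx <- sample.int(n)
  out <- list()
  for (start in seq(1, n, by = pool)) {
    chunk <- idx[start:min(start + pool - 1, n)]
    chunk <- chunk[order(src_lens[chunk])]
    cur <- integer(0); ms <- 0L; mt <- 0L
    for (i in chunk) {
      ms2 <- max(ms, src_lens[i]); mt2 <- max(mt, tgt_lens[i] + 1L)
      if (length(cur) && (length(cur) + 1L) * (ms2 + mt2) > batch_tokens) {
        out[[length(out) + 1L]] <- cur
        cur <- integer(0); ms2 <- src_lens[i]; mt2 <- tgt_lens[i] + 1L
      }
      cur <- c(cur, i); ms <- ms2; mt <- mt2
    }
    if (length(cur)) out[[length(out) + 1L]] <- cur
  }
  out
}

## Per-corpus batch stream with wraparound reshuffling (epoch boundaries).
batch_stream <- function(enc, batch_tokens) {
  env <- new.env(parent = emptyenv())
  env$enc <- enc
  env$sl <- lengths(enc$src); env$tl <- lengths(enc$tgt)
  env$queue <- list()
  env$next_batch <- function() {
    if (!length(env$queue)) {
      env$queue <- plan_batches(env$sl, env$tl, batch_tokens)
    }
    idx <- env$queue[[1]]
    env$queue <- env$queue[-1]
    make_batch(env$enc$src[idx], env$enc$tgt[idx])
  }
  env
}

## Teacher-forced validation loss and token accuracy.
validate_model <- function(model, enc, max_records = 512L, batch_tokens = 2048L) {
  n <- min(enc$n, max_records)
  idx <- seq_len(n)
  tot_loss <- 0; tot_acc <- 0; tot_tok <- 0
  for (start in seq(1, n, by = 64L)) {
    sel <- idx[start:min(start + 63L, n)]
    b <- make_batch(enc$src[sel], enc$tgt[sel])
    r <- transformer_fb(model, b, grads = FALSE, train = FALSE)
    tot_loss <- tot_loss + r$loss * r$n_tokens
    tot_acc <- tot_acc + r$acc * r$n_tokens
    tot_tok <- tot_tok + r$n_tokens
  }
  list(loss = tot_loss / tot_tok, acc = tot_acc / tot_tok)
}

add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) a[[nm]] <- a[[nm]] + b[[nm]]
  a
}

#' Train a transformer under a given regime
#'
#' Regimes: `"single"` trains on one corpus; `"mtl"` trains on a weighted
#' [multitask_mixture()] with deterministic interleaving (see
#' [sample_multitask_batches()]); `"stl"` first trains on the general corpus,
#' then continues from those weights on the specialized corpus (the step
#' counter, and hence the noam schedule, continues across the phases).
#' Validation uses teacher-forced token accuracy; the best-scoring parameters
#' are kept and early stopping triggers after `schedule$patience`
#' non-improving validations.
#'
#' @param config a [model_config()].
#' @param schedule a [training_schedule()].
#' @param data an encoded corpus ([encode_corpus()]) for `"single"`; a
#'   `multitask_mixture` for `"mtl"`; a list
#'   `list(general = ..., specialized = ...)` for `"stl"`.
#' @param regime `"single"`, `"mtl"` or `"stl"`.
#' @param valid optional encoded validation corpus.
#' @param init_model optional warm-start model (used internally by STL).
#' @param start_step step offset for the noam schedule.
#' @param steps optional override of `schedule$max_steps`.
#' @param vocab_size combined vocabulary size (defaults to the largest id
#'   seen in `data`; pass [vocab_size()] of the tokenizer pair in normal use).
#' @param quiet suppress progress messages.
#' @return list with `model`, `history` (data.frame of step, lr, loss,
#'   corpus) and `val_history`.
#' @export
train_transformer <- function(config, schedule, data,
                              regime = c("single", "mtl", "stl"),
                              valid = NULL, init_model = NULL,
                              start_step = 0L, steps = NULL,
                              vocab_size = NULL, quiet = FALSE) {
  regime <- match.arg(regime)
  if (regime == "stl") {
    stopifnot(all(c("general", "specialized") %in% names(data)))
    ph1 <- train_transformer(config, schedule, data$general, "single",
                             valid = NULL, init_model = init_model,
                             start_step = start_step, steps = steps,
                             vocab_size = vocab_size, quiet = quiet)
    ph2 <- train_transformer(config, schedule, data$specialized, "single",
                             valid = valid, init_model = ph1$model,
                             start_step = start_step + nrow(ph1$history),
                             steps = steps, vocab_size = vocab_size,
                             quiet = quiet)
    ph2$history <- rbind(cbind(ph1$history, phase = "general"),
                         cbind(ph2$history, phase = "specialized"))
    return(ph2)
  }
  n_steps <- if (is.null(steps)) schedule$max_steps else as.integer(steps)
  if (regime == "mtl") {
    stopifnot(inherits(data, "multitask_mixture"))
    if (any(vapply(data$corpora, function(e) e$n, numeric(1)) == 0)) {
      stop("train_transformer: empty corpus in mixture")
    }
    corpus_of <- sample_multitask_batches(data, n_steps * schedule$accum_count,
                                          seed = schedule$seed)
    streams <- lapply(data$corpora, batch_stream,
                      batch_tokens = schedule$batch_tokens)
    vs <- vapply(data$corpora, function(e) {
      max(unlist(e$src, use.names = FALSE), unlist(e$tgt, use.names = FALSE))
    }, numeric(1))
  } else {
    corpus_of <- rep("train", n_steps * schedule$accum_count)
    streams <- list(train = batch_stream(data, schedule$batch_tokens))
    vs <- max(unlist(data$src, use.names = FALSE),
              unlist(data$tgt, use.names = FALSE))
  }
  model <- init_model
  set.seed(schedule$seed + start_step)
  if (is.null(model)) {
    nv <- if (is.null(vocab_size)) as.integer(max(vs)) else as.integer(vocab_size)
    model <- init_transformer(config, vocab_size = nv, seed = schedule$seed)
  }
  if (max(vs) > model$vocab_size) {
    stop("train_transformer: data contains ids outside the model vocabulary")
  }
  ## private copies: the optimizer updates parameters in place
  model$params <- lapply(model$params, function(x) x + 0)
  opt <- adam_init(model$params)
  hist <- data.frame(step = integer(0), lr = numeric(0), loss = numeric(0),
                     corpus = character(0))
  val_hist <- data.frame(step = integer(0), loss = numeric(0), acc = numeric(0))
  best <- list(acc = -Inf, params = NULL, step = 0L)
  bad <- 0L
  micro <- 0L
  ## evenly spaced snapshots over the last quarter of training, for
  ## checkpoint averaging
  navg <- if (is.null(schedule$avg_checkpoints)) 0L else schedule$avg_checkpoints
  snap_at <- if (navg > 0) {
    unique(round(seq(n_steps * 0.75, n_steps, length.out = navg)))
  } else integer(0)
  snaps <- list()
  for (s in seq_len(n_steps)) {
    step <- start_step + s
    lr <- noam_lr(step, schedule, config$model_dim)
    gsum <- NULL; lsum <- 0
    cname <- ""
    for (a in seq_len(schedule$accum_count)) {
      micro <- micro + 1L
      cname <- corpus_of[micro]
      b <- streams[[cname]]$next_batch()
      r <- transformer_fb(model, b, grads = TRUE, train = TRUE)
      gsum <- add_grads(gsum, r$grads)
      lsum <- lsum + r$loss
    }
    if (schedule$accum_count > 1) {
      for (nm in names(gsum)) gsum[[nm]] <- gsum[[nm]] / schedule$accum_count
    }
    opt$t <- opt$t + 1L
    adam_step_cpp(model$params, gsum, opt$m, opt$v, opt$t, lr,
                  schedule$adam_betas[1], schedule$adam_betas[2], 1e-9)
    if (s %in% snap_at) {
      snaps[[length(snaps) + 1L]] <- lapply(model$params, function(x) x + 0)
    }
    hist[nrow(hist) + 1L, ] <- list(step, lr, lsum / schedule$accum_count, cname)
    if (!is.null(valid) && schedule$valid_every > 0 &&
        (s %% schedule$valid_every == 0 || s == n_steps)) {
      v <- validate_model(model, valid)
      val_hist[nrow(val_hist) + 1L, ] <- list(step, v$loss, v$acc)
      if (!quiet) {
        message(sprintf("step %d  lr %.5f  train loss %.4f  val loss %.4f  val acc %.4f",
                        step, lr, lsum / schedule$accum_count, v$loss, v$acc))
      }
      if (v$acc > best$acc) {
        ## deep copy: parameters are otherwise updated in place
        best <- list(acc = v$acc,
                     params = lapply(model$params, function(x) x + 0),
                     step = step)
        bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= schedule$patience) {
          if (!quiet) message("early stopping at step ", step)
          break
        }
      }
    } else if (!quiet && s %% 100 == 0) {
      message(sprintf("step %d  lr %.5f  loss %.4f", step, lr,
                      lsum / schedule$accum_count))
    }
  }
  if (length(snaps) > 1) {
    ## checkpoint averaging (training ran to completion)
    model$params <- lapply(names(model$params), function(nm) {
      Reduce(`+`, lapply(snaps, `[[`, nm)) / length(snaps)
    })
    names(model$params) <- names(snaps[[1]])
  } else if (!is.null(best$params)) {
    model$params <- best$params
  }
  list(model = model, history = hist, val_history = val_hist)
}
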
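## Model/training configuration, the noam learning-rate schedule, Adam, and
## weighted multi-task batch scheduling.

#' Transformer model configuration
#'
#' The reference configuration mirrors the published hyperparameters
#' (4 layers, model dimension 384, 8 heads, feed-forward 2048, dropout 0.1,
#' label smoothing 0). The default here is a desk-scale configuration
#' (2 layers, dimension 128, 4 heads, feed-forward 512) suited to CPU
#' training on the bundled synthetic corpora.
#'
#' @param layers number of encoder and decoder layers.
#' @param model_dim embedding/attention dimension (divisible by `heads`).
#' @param heads attention heads.
#' @param ff_dim feed-forward inner dimension.
#' @param dropout dropout fraction.
#' @param label_smoothing label-smoothing mass.
#' @param max_len maximum sequence length for positional encodings.
#' @return a `model_config` list.
#' @export
model_config <- function(layers = 2, model_dim = 128, heads = 4,
                         ff_dim = 512, dropout = 0.1, label_smoothing = 0.0,
                         max_len = 256) {
  stopifnot(layers >= 1, model_dim >= 1, heads >= 1, ff_dim >= 1,
            model_dim %% heads == 0)
  structure(list(layers = as.integer(layers), model_dim = as.integer(model_dim),
                 heads = as.integer(heads), ff_dim = as.integer(ff_dim),
                 dropout = dropout, label_smoothing = label_smoothing,
                 max_len = as.integer(max_len)),
            class = "model_config")
}

#' Reference-scale model configuration
#'
#' The published hyperparameters: 4 layers, dimension 384, 8 heads,
#' feed-forward 2048.
#' @return a `model_config`.
#' @export
reference_config <- function() {
  model_config(layers = 4, model_dim = 384, heads = 8, ff_dim = 2048)
}

#' Training schedule
#'
#' Reference values follow the published run (base learning rate 4, 8000
#' warmup steps, 200 000 training steps, token batches of 6144 with 4-step
#' gradient accumulation, Adam betas 0.9/0.998, seed 42). Defaults here are
#' desk-scale values for CPU training on the synthetic benchmark.
#'
#' @param base_lr noam base learning rate.
#' @param warmup_steps linear warmup length (>= 1).
#' @param max_steps total optimizer steps (>= `warmup_steps`).
#' @param batch_tokens approximate source+target token budget per batch.
#' @param accum_count gradient-accumulation micro-batches per step.
#' @param adam_betas length-2 numeric.
#' @param seed integer seed for parameter init, batching and dropout.
#' @param valid_every validate every this many steps (0 = never).
#' @param patience early-stopping patience in validations.
#' @param avg_checkpoints average the parameters of this many evenly spaced
#'   snapshots from the last quarter of training (0, the default, disables).
#'   Checkpoint averaging smooths optimization noise; it raises absolute
#'   accuracy for text-blind models in particular, so the bundled
#'   model-comparison experiments leave it off to keep every cell's
#'   training identical and minimal.
#' @return a `training_schedule` list.
#' @export
training_schedule <- function(base_lr = 0.6, warmup_steps = 250,
                              max_steps = 1900, batch_tokens = 1536,
                              accum_count = 1, adam_betas = c(0.9, 0.998),
                              seed = 42, valid_every = 100, patience = 5,
                              avg_checkpoints = 0) {
  stopifnot(warmup_steps >= 1, max_steps >= warmup_steps)
  structure(list(base_lr = base_lr, warmup_steps = as.integer(warmup_steps),
                 max_steps = as.integer(max_steps),
                 batch_tokens = as.integer(batch_tokens),
                 accum_count = as.integer(accum_count),
                 adam_betas = adam_betas, seed = as.integer(seed),
                 valid_every = as.integer(valid_every),
                 patience = as.integer(patience),
                 avg_checkpoints = as.integer(avg_checkpoints)),
            class = "training_schedule")
}

#' noam learning rate
#'
#' `base_lr * model_dim^(-0.5) * min(step^(-0.5), step * warmup^(-1.5))`:
#' linear warmup to the peak at `step == warmup_steps`, then inverse-
#' square-root decay, scaled by the model dimension.
#'
#' @param step optimizer step (>= 1); vectorized.
#' @param schedule a `training_schedule` (uses `base_lr`, `warmup_steps`).
#' @param model_dim model dimension.
#' @return learning rate(s).
#' @export
noam_lr <- function(step, schedule, model_dim) {
  if (any(step < 1)) stop("noam_lr: step must be >= 1")
  w <- schedule$warmup_steps
  schedule$base_lr * model_dim^(-0.5) * pmin(step^(-0.5), step * w^(-1.5))
}

## ---- Adam ----------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, betas = c(0.9, 0.998),
                      eps = 1e-9) {
  state$t <- state$t + 1L
  b1 <- betas[1]; b2 <- betas[2]
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  step_size <- lr / bc1
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    m <- b1 * state$m[[nm]] + (1 - b1) * g
    v <- b2 * state$v[[nm]] + (1 - b2) * g * g
    state$m[[nm]] <- m
    state$v[[nm]] <- v
    params[[nm]] <- params[[nm]] - step_size * m / (sqrt(v / bc2) + eps)
  }
  list(params = params, state = state)
}

## ---- multi-task mixing ----------------------------------------------------

#' Build a weighted multi-task mixture
#'
#' @param corpora named list of encoded corpora (see [encode_corpus()]).
#' @param weights positive integer sampling weights aligned with `corpora`
#'   (the reference regime weights the specialized corpus 1 against the
#'   general corpus 9).
#' @return a `multitask_mixture`.
#' @export
multitask_mixture <- function(corpora, weights) {
  stopifnot(length(corpora) == length(weights), length(corpora) >= 1,
            !is.null(names(corpora)))
  if (any(weights < 1)) stop("multitask_mixture: weights must be >= 1")
  structure(list(corpora = corpora, weights = as.integer(weights)),
            class = "multitask_mixture")
}

#' Deterministic weighted interleaving of corpus batches
#'
#' Per cycle of `sum(weights)` batches, exactly `weights[i]` batches come
#' from corpus `i`, interleaved in a fixed round-robin pattern (weights 1:1
#' alternate strictly). Within each corpus, examples are shuffled with the
#' seed and iterated with wraparound reshuffling, so a full corpus epoch is
#' visited before any example repeats.
#'
#' @param mixture a `multitask_mixture`.
#' @param n_batches number of batch slots to schedule.
#' @param seed integer seed (reserved; the schedule itself is deterministic).
#' @return character vector of corpus names, length `n_batches`.
#' @export
sample_multitask_batches <- function(mixture, n_batches, seed = 42) {
  w <- mixture$weights
  nm <- names(mixture$corpora)
  ## round-robin interleave: corpus i appears w[i] times per cycle, spread out
  cyc <- do.call(rbind, lapply(seq_along(nm), function(i) {
    data.frame(name = nm[i], at = (seq_len(w[i]) - 0.5) / w[i],
               pri = i, stringsAsFactors = FALSE)
  }))
  cyc <- cyc[order(cyc$at, cyc$pri), ]
  rep_len(cyc$name, n_batches)
}
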
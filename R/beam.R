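## Beam-search decoding.
##
## `beam_search()` is a generic n-best beam over any autoregressive scorer
## (used directly by the toy-model enumeration tests); `decode_transformer()`
## is the batched transformer decoder with cached self-attention keys/values
## and precomputed cross-attention projections, so each generated token costs
## one incremental forward step.

#' Generic beam search over an autoregressive scorer
#'
#' @param step_fn function taking a list of integer prefix vectors (each
#'   starting with `bos`) and returning a matrix of per-token log-probability
#'   rows (one row per prefix, normalized over the vocabulary).
#' @param vocab_size vocabulary size.
#' @param bos,eos begin/end-of-sequence ids.
#' @param beam_width beam width (>= `n_best`).
#' @param n_best number of hypotheses to return.
#' @param max_len maximum generated length (excluding BOS/EOS).
#' @return data.frame with one row per hypothesis: `rank`, `tokens`
#'   (list column of id vectors, no BOS/EOS), `log_prob`, `confidence
#'   = exp(log_prob)`, sorted by descending log-probability (ties: shorter
#'   sequence first, then lexicographic token order).
#' @export
beam_search <- function(step_fn, vocab_size, bos = 2L, eos = 3L,
                        beam_width = 5L, n_best = 2L, max_len = 32L) {
  if (n_best > beam_width) stop("beam_search: n_best > beam_width")
  active <- list(list(ids = c(bos), lp = 0))
  finished <- list()
  for (t in seq_len(max_len)) {
    lp <- step_fn(lapply(active, `[[`, "ids"))
    cand_lp <- unlist(lapply(seq_along(active), function(i) {
      active[[i]]$lp + lp[i, ]
    }))
    cand_beam <- rep(seq_along(active), each = vocab_size)
    cand_tok <- rep(seq_len(vocab_size), times = length(active))
    keep <- order(-cand_lp)[seq_len(min(beam_width, length(cand_lp)))]
    nxt <- list()
    for (k in keep) {
      hyp <- list(ids = c(active[[cand_beam[k]]]$ids, cand_tok[k]),
                  lp = cand_lp[k])
      if (cand_tok[k] == eos) finished[[length(finished) + 1]] <- hyp
      else nxt[[length(nxt) + 1]] <- hyp
    }
    active <- nxt
    if (!length(active) || length(finished) >= beam_width) break
  }
  for (h in active) finished[[length(finished) + 1]] <- h
  toks <- lapply(finished, function(h) {
    ids <- h$ids[-1]
    if (length(ids) && ids[length(ids)] == eos) ids <- ids[-length(ids)]
    ids
  })
  lps <- vapply(finished, `[[`, numeric(1), "lp")
  key <- vapply(toks, function(x) paste(sprintf("%06d", x), collapse = " "),
                character(1))
  ord <- order(-lps, lengths(toks), key)[seq_len(min(n_best, length(lps)))]
  data.frame(rank = seq_along(ord),
             tokens = I(toks[ord]),
             log_prob = lps[ord],
             confidence = exp(lps[ord]))
}

## ---- incremental transformer decoding -------------------------------------

## Encoder-only forward pass (inference mode), returning the memory matrix.
enc_forward <- function(model, src_flat, B, Ls, src_len) {
  p <- model$params; cfg <- model$config
  X <- embed_rows(model, src_flat, Ls, B)
  for (l in seq_len(cfg$layers)) {
    pn <- function(x) paste0("enc", l, "_", x)
    ln1 <- ln_f(X, p[[pn("ln1g")]], p[[pn("ln1b")]])
    at <- mha_f(ln1$y, ln1$y, p[[pn("Wq")]], p[[pn("Wk")]], p[[pn("Wv")]],
                p[[pn("Wo")]], cfg$heads, B, Ls, Ls, src_len, causal = FALSE)
    X <- X + at$out
    ln3 <- ln_f(X, p[[pn("ln3g")]], p[[pn("ln3b")]])
    ff <- ffn_f(ln3$y, p[[pn("W1")]], p[[pn("b1")]], p[[pn("W2")]], p[[pn("b2")]])
    X <- X + ff$out
  }
  ln_f(X, p$lnEg, p$lnEb)$y
}

## One incremental decoder step for the first M cache rows. `cache` is an
## environment holding per-layer arrays self_k/self_v (Mcap, T, d) and the
## cross projections; arrays are updated in place at position t.
dec_step <- function(model, ids, t, M, cache, hyp_rec, Ls, src_len,
                     cross_mask) {
  p <- model$params; cfg <- model$config
  d <- cfg$model_dim; h <- cfg$heads; dh <- d / h
  hm <- cache$hm
  rowsM <- seq_len(M)
  x <- p$E[ids, , drop = FALSE] * sqrt(d) +
    matrix(model$pos[t, ], M, d, byrow = TRUE)
  scale <- 1 / sqrt(dh)
  expand_h <- cache$expand_h
  for (l in seq_len(cfg$layers)) {
    pn <- function(x) paste0("dec", l, "_", x)
    xn <- ln_f(x, p[[pn("ln1g")]], p[[pn("ln1b")]])$y
    q <- xn %*% p[[pn("Wq")]]
    cache$self_k[[l]][rowsM, t, ] <- xn %*% p[[pn("Wk")]]
    cache$self_v[[l]][rowsM, t, ] <- xn %*% p[[pn("Wv")]]
    S <- array(0, c(M, h, t))
    for (tt in seq_len(t)) {
      Kt <- matrix(cache$self_k[[l]][rowsM, tt, ], M, d)
      S[, , tt] <- (q * Kt) %*% hm * scale
    }
    ctx <- matrix(0, M, d)
    for (hh in seq_len(h)) {
      Sh <- matrix(S[, hh, ], M, t)
      Ph <- exp(Sh - row_max(Sh)); Ph <- Ph / rowSums(Ph)
      S[, hh, ] <- Ph
    }
    for (tt in seq_len(t)) {
      Vt <- matrix(cache$self_v[[l]][rowsM, tt, ], M, d)
      ctx <- ctx + Vt * matrix(S[, , tt], M, h)[, expand_h]
    }
    x <- x + ctx %*% p[[pn("Wo")]]
    ## cross attention over the (fixed) encoder memory
    xn <- ln_f(x, p[[pn("ln2g")]], p[[pn("ln2b")]])$y
    q <- xn %*% p[[pn("cWq")]]
    S <- array(0, c(M, h, Ls))
    for (j in seq_len(Ls)) {
      rows <- (hyp_rec - 1) * Ls + j
      S[, , j] <- (q * cache$crossK[[l]][rows, , drop = FALSE]) %*% hm * scale
    }
    ctx <- matrix(0, M, d)
    for (hh in seq_len(h)) {
      Sh <- matrix(S[, hh, ], M, Ls)
      Sh[cross_mask] <- -Inf
      Ph <- exp(Sh - row_max(Sh)); Ph <- Ph / rowSums(Ph)
      S[, hh, ] <- Ph
    }
    for (j in seq_len(Ls)) {
      rows <- (hyp_rec - 1) * Ls + j
      ctx <- ctx + cache$crossV[[l]][rows, , drop = FALSE] *
        matrix(S[, , j], M, h)[, expand_h]
    }
    x <- x + ctx %*% p[[pn("cWo")]]
    xn <- ln_f(x, p[[pn("ln3g")]], p[[pn("ln3b")]])$y
    ff <- ffn_f(xn, p[[pn("W1")]], p[[pn("b1")]], p[[pn("W2")]], p[[pn("b2")]])
    x <- x + ff$out
  }
  xn <- ln_f(x, p$lnDg, p$lnDb)$y
  xn %*% p$Wout + cbv(p$bout, M)
}

#' Beam-search decode a batch of sources with a trained transformer
#'
#' Batched n-best beam search with cached decoder self-attention and
#' precomputed cross-attention projections. Hypothesis confidence is the
#' product of its token probabilities, `exp(log_prob)`.
#'
#' @param model an `enz_transformer`.
#' @param sources list of encoded source id vectors (see [encode_source()]).
#' @param beam_width beam width (>= `n_best`).
#' @param n_best hypotheses returned per source.
#' @param max_len maximum product length in tokens.
#' @param chunk number of sources decoded simultaneously.
#' @param pad,bos,eos special-token ids.
#' @return data.frame with columns `source_index`, `rank`, `ids` (list
#'   column), `log_prob`, `confidence`.
#' @export
decode_transformer <- function(model, sources, beam_width = 5L, n_best = 2L,
                               max_len = 48L, chunk = 250L,
                               pad = 1L, bos = 2L, eos = 3L) {
  if (n_best > beam_width) stop("decode_transformer: n_best > beam_width")
  out <- list()
  for (start in seq(1, length(sources), by = chunk)) {
    sel <- start:min(start + chunk - 1, length(sources))
    res <- decode_chunk(model, sources[sel], beam_width, n_best, max_len,
                        pad, bos, eos)
    res$source_index <- sel[res$source_index]
    out[[length(out) + 1]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

decode_chunk <- function(model, sources, beam_width, n_best, max_len,
                         pad, bos, eos) {
  p <- model$params; cfg <- model$config
  d <- cfg$model_dim; h <- cfg$heads; dh <- d / h
  R <- length(sources)
  Ls <- max(lengths(sources))
  src_len <- lengths(sources)
  mem <- enc_forward(model, pad_flat(sources, Ls, pad), R, Ls, src_len)
  cache <- new.env(parent = emptyenv())
  cache$crossK <- list(); cache$crossV <- list()
  for (l in seq_len(cfg$layers)) {
    cache$crossK[[l]] <- mem %*% p[[paste0("dec", l, "_cWk")]]
    cache$crossV[[l]] <- mem %*% p[[paste0("dec", l, "_cWv")]]
  }
  Mcap <- R * beam_width
  cache$self_k <- lapply(seq_len(cfg$layers),
                         function(l) array(0, c(Mcap, max_len + 1, d)))
  cache$self_v <- lapply(seq_len(cfg$layers),
                         function(l) array(0, c(Mcap, max_len + 1, d)))
  cache$hm <- local({
    m <- matrix(0, d, h)
    for (hh in seq_len(h)) m[((hh - 1) * dh + 1):(hh * dh), hh] <- 1
    m
  })
  cache$expand_h <- rep(seq_len(h), each = dh)
  hyp_rec <- seq_len(R)
  hyp_ids <- lapply(seq_len(R), function(i) integer(0))
  hyp_lp <- rep(0, R)
  last_tok <- rep(bos, R)
  finished <- lapply(seq_len(R), function(i) list())
  for (t in seq_len(max_len + 1)) {
    M <- length(hyp_rec)
    if (!M) break
    if (t > max_len) {   # force-finish whatever is still active
      for (i in seq_len(M)) {
        r <- hyp_rec[i]
        finished[[r]][[length(finished[[r]]) + 1]] <-
          list(ids = hyp_ids[[i]], lp = hyp_lp[i])
      }
      break
    }
    cross_mask <- outer(hyp_rec, seq_len(Ls), function(r, j) j > src_len[r])
    logits <- dec_step(model, last_tok, t, M, cache, hyp_rec, Ls, src_len,
                       cross_mask)
    mx <- row_max(logits)
    lp <- logits - mx - log(rowSums(exp(logits - mx)))
    V <- ncol(lp)
    new_rec <- integer(0); new_ids <- list(); new_lp <- numeric(0)
    new_last <- integer(0); new_parent <- integer(0)
    for (r in unique(hyp_rec)) {
      rows <- which(hyp_rec == r)
      cand_lp <- rep(hyp_lp[rows], each = V) +
        as.vector(t(lp[rows, , drop = FALSE]))
      k <- order(-cand_lp)[seq_len(min(beam_width, length(cand_lp)))]
      for (kk in k) {
        i <- rows[(kk - 1) %/% V + 1]
        v <- (kk - 1) %% V + 1
        if (v == eos) {
          finished[[r]][[length(finished[[r]]) + 1]] <-
            list(ids = hyp_ids[[i]], lp = cand_lp[kk])
        } else {
          new_rec <- c(new_rec, r)
          new_ids[[length(new_ids) + 1]] <- c(hyp_ids[[i]], v)
          new_lp <- c(new_lp, cand_lp[kk])
          new_last <- c(new_last, v)
          new_parent <- c(new_parent, i)
        }
      }
    }
    ## prune hypotheses that can no longer enter the record's n_best
    if (length(new_rec)) {
      keep <- vapply(seq_along(new_rec), function(i) {
        fin <- finished[[new_rec[i]]]
        length(fin) < n_best ||
          new_lp[i] > min(vapply(fin, `[[`, numeric(1), "lp"))
      }, logical(1))
      new_rec <- new_rec[keep]; new_ids <- new_ids[keep]
      new_lp <- new_lp[keep]; new_last <- new_last[keep]
      new_parent <- new_parent[keep]
    }
    if (length(new_parent)) {
      tseq <- seq_len(t)
      for (l in seq_len(cfg$layers)) {
        cache$self_k[[l]][seq_along(new_parent), tseq, ] <-
          cache$self_k[[l]][new_parent, tseq, ]
        cache$self_v[[l]][seq_along(new_parent), tseq, ] <-
          cache$self_v[[l]][new_parent, tseq, ]
      }
    }
    hyp_rec <- new_rec; hyp_ids <- new_ids; hyp_lp <- new_lp
    last_tok <- new_last
  }
  rows <- list()
  for (r in seq_len(R)) {
    fin <- finished[[r]]
    if (!length(fin)) next
    lps <- vapply(fin, `[[`, numeric(1), "lp")
    toks <- lapply(fin, `[[`, "ids")
    key <- vapply(toks, function(x) paste(sprintf("%06d", x), collapse = " "),
                  character(1))
    ord <- order(-lps, lengths(toks), key)[seq_len(min(n_best, length(fin)))]
    rows[[length(rows) + 1]] <- data.frame(
      source_index = r, rank = seq_along(ord),
      ids = I(toks[ord]), log_prob = lps[ord],
      confidence = exp(lps[ord]))
  }
  do.call(rbind, rows)
}
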
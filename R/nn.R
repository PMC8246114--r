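## Encoder-decoder transformer with hand-written backpropagation.
##
## Pre-norm residual blocks (LayerNorm -> sublayer -> dropout -> add), scaled
## dot-product multi-head attention, ReLU feed-forward, sinusoidal positional
## encodings, shared source/target embedding, untied output projection.
## Batches are flattened sequence-major into (B*L) x d matrices so that all
## row-wise operations and projections run as single BLAS calls; only the
## attention score/context products loop over sequences and heads.

cbv <- function(v, n) rep(v, rep.int(n, length(v)))   # broadcast a length-d vector over n rows

glorot <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -s, s), nin, nout)
}

sinusoid_pos <- function(max_len, d) {
  pos <- matrix(0, max_len, d)
  p <- seq_len(max_len) - 1
  for (i in seq_len(d %/% 2)) {
    f <- 1 / 10000^((2 * (i - 1)) / d)
    pos[, 2 * i - 1] <- sin(p * f)
    pos[, 2 * i] <- cos(p * f)
  }
  pos
}

#' Initialize a transformer model
#'
#' @param config a [model_config()].
#' @param vocab_size combined vocabulary size (see [vocab_size()]).
#' @param seed integer seed for Glorot-uniform initialization.
#' @return an `enz_transformer` (parameter list + config + positional table).
#' @export
init_transformer <- function(config, vocab_size, seed = 42) {
  d <- config$model_dim; ff <- config$ff_dim; V <- vocab_size
  params <- list()
  with_seed(seed, {
    params$E <- matrix(stats::rnorm(V * d, sd = d^-0.5), V, d)
    for (side in c("enc", "dec")) {
      for (l in seq_len(config$layers)) {
        p <- function(x) paste0(side, l, "_", x)
        params[[p("ln1g")]] <- rep(1, d); params[[p("ln1b")]] <- rep(0, d)
        params[[p("Wq")]] <- glorot(d, d); params[[p("Wk")]] <- glorot(d, d)
        params[[p("Wv")]] <- glorot(d, d); params[[p("Wo")]] <- glorot(d, d)
        if (side == "dec") {
          params[[p("ln2g")]] <- rep(1, d); params[[p("ln2b")]] <- rep(0, d)
          params[[p("cWq")]] <- glorot(d, d); params[[p("cWk")]] <- glorot(d, d)
          params[[p("cWv")]] <- glorot(d, d); params[[p("cWo")]] <- glorot(d, d)
        }
        params[[p("ln3g")]] <- rep(1, d); params[[p("ln3b")]] <- rep(0, d)
        params[[p("W1")]] <- glorot(d, ff); params[[p("b1")]] <- rep(0, ff)
        params[[p("W2")]] <- glorot(ff, d); params[[p("b2")]] <- rep(0, d)
      }
    }
    params$lnEg <- rep(1, d); params$lnEb <- rep(0, d)
    params$lnDg <- rep(1, d); params$lnDb <- rep(0, d)
    params$Wout <- glorot(d, V); params$bout <- rep(0, V)
  })
  structure(list(params = params, config = config, vocab_size = V,
                 pos = sinusoid_pos(config$max_len, d)),
            class = "enz_transformer")
}

#' @export
print.enz_transformer <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat("<enz_transformer> layers:", x$config$layers,
      "dim:", x$config$model_dim, "heads:", x$config$heads,
      "vocab:", x$vocab_size, sprintf("params: %.2fM\n", np / 1e6))
  invisible(x)
}

## ---- layers ---------------------------------------------------------------

ln_f <- function(x, g, b, eps = 1e-6) {
  n <- nrow(x)
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv
  list(y = xhat * cbv(g, n) + cbv(b, n), xhat = xhat, inv = inv)
}

ln_b <- function(dy, cache, g) {
  n <- nrow(dy)
  xhat <- cache$xhat
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxhat <- dy * cbv(g, n)
  dx <- cache$inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = dg, db = db)
}

row_max <- function(S) S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]

mha_f <- function(Xq, Xkv, Wq, Wk, Wv, Wo, h, B, Lq, Lkv, kv_len,
                  causal = FALSE) {
  d <- ncol(Wq); dh <- d / h; scale <- 1 / sqrt(dh)
  Q <- Xq %*% Wq; K <- Xkv %*% Wk; V <- Xkv %*% Wv
  Ctx <- matrix(0, nrow(Xq), d)
  P <- vector("list", B * h)
  for (b in seq_len(B)) {
    rq <- ((b - 1) * Lq + 1):(b * Lq)
    rk <- ((b - 1) * Lkv + 1):(b * Lkv)
    kl <- kv_len[b]
    for (hh in seq_len(h)) {
      cols <- ((hh - 1) * dh + 1):(hh * dh)
      S <- tcrossprod(Q[rq, cols, drop = FALSE],
                      K[rk, cols, drop = FALSE]) * scale
      if (kl < Lkv) S[, (kl + 1):Lkv] <- -Inf
      if (causal) S[upper.tri(S)] <- -Inf
      Pm <- exp(S - row_max(S))
      Pm <- Pm / rowSums(Pm)
      P[[(b - 1) * h + hh]] <- Pm
      Ctx[rq, cols] <- Pm %*% V[rk, cols, drop = FALSE]
    }
  }
  list(out = Ctx %*% Wo, Q = Q, K = K, V = V, P = P, Ctx = Ctx,
       Xq = Xq, Xkv = Xkv, h = h, B = B, Lq = Lq, Lkv = Lkv, scale = scale)
}

mha_b <- function(dOut, cc, Wq, Wk, Wv, Wo) {
  h <- cc$h; B <- cc$B; Lq <- cc$Lq; Lkv <- cc$Lkv
  d <- ncol(Wq); dh <- d / h
  dCtx <- tcrossprod(dOut, Wo)
  dWo <- crossprod(cc$Ctx, dOut)
  dQ <- matrix(0, nrow(cc$Q), d); dK <- matrix(0, nrow(cc$K), d)
  dV <- matrix(0, nrow(cc$K), d)
  for (b in seq_len(B)) {
    rq <- ((b - 1) * Lq + 1):(b * Lq)
    rk <- ((b - 1) * Lkv + 1):(b * Lkv)
    for (hh in seq_len(h)) {
      cols <- ((hh - 1) * dh + 1):(hh * dh)
      Pm <- cc$P[[(b - 1) * h + hh]]
      dC <- dCtx[rq, cols, drop = FALSE]
      dP <- tcrossprod(dC, cc$V[rk, cols, drop = FALSE])
      dS <- Pm * (dP - rowSums(Pm * dP)) * cc$scale
      dQ[rq, cols] <- dS %*% cc$K[rk, cols, drop = FALSE]
      dK[rk, cols] <- crossprod(dS, cc$Q[rq, cols, drop = FALSE])
      dV[rk, cols] <- crossprod(Pm, dC)
    }
  }
  list(dXq = tcrossprod(dQ, Wq),
       dXkv = tcrossprod(dK, Wk) + tcrossprod(dV, Wv),
       dWq = crossprod(cc$Xq, dQ), dWk = crossprod(cc$Xkv, dK),
       dWv = crossprod(cc$Xkv, dV), dWo = dWo)
}

ffn_f <- function(X, W1, b1, W2, b2) {
  H <- X %*% W1
  H <- H + cbv(b1, nrow(X))
  H[H < 0] <- 0
  list(out = H %*% W2 + cbv(b2, nrow(X)), H = H, X = X)
}

ffn_b <- function(dOut, cc, W1, W2) {
  dH <- tcrossprod(dOut, W2)
  dH[cc$H <= 0] <- 0
  list(dX = tcrossprod(dH, W1),
       dW1 = crossprod(cc$X, dH), db1 = colSums(dH),
       dW2 = crossprod(cc$H, dOut), db2 = colSums(dOut))
}

drop_mask <- function(nr, nc, p) {
  if (p <= 0) return(NULL)
  matrix((stats::runif(nr * nc) > p) / (1 - p), nr, nc)
}

## ---- batch assembly -------------------------------------------------------

## Pad integer sequences to a common length and flatten sequence-major.
pad_flat <- function(seqs, L, pad = 1L) {
  B <- length(seqs)
  m <- matrix(pad, B, L)
  for (b in seq_len(B)) {
    s <- seqs[[b]]
    if (length(s)) m[b, seq_along(s)] <- s
  }
  as.vector(t(m))
}

## Build a training batch from encoded src/tgt id sequences.
make_batch <- function(src, tgt, pad = 1L, bos = 2L, eos = 3L) {
  B <- length(src)
  Ls <- max(lengths(src))
  tin <- lapply(tgt, function(s) c(bos, s))
  tout <- lapply(tgt, function(s) c(s, eos))
  Lt <- max(lengths(tin))
  list(B = B, Ls = Ls, Lt = Lt,
       src = pad_flat(src, Ls, pad),
       src_len = lengths(src),
       tgt_in = pad_flat(tin, Lt, pad),
       tgt_out = pad_flat(tout, Lt, pad),
       tgt_mask = pad_flat(lapply(tin, function(s) rep(1L, length(s))), Lt, 0L) == 1L,
       tgt_len = lengths(tin))
}

## ---- forward / backward ---------------------------------------------------

embed_rows <- function(model, ids, L, B) {
  d <- model$config$model_dim
  X <- model$params$E[ids, , drop = FALSE] * sqrt(d)
  X + model$pos[rep(seq_len(L), B), , drop = FALSE]
}

## Full fused forward+backward over one batch. Returns loss, token accuracy
## and (if grads) the gradient list aligned with model$params. Two engines
## compute identical results (asserted in the tests): the compiled
## RcppArmadillo path (default) and the reference R path.
transformer_fb <- function(model, batch, grads = TRUE, train = TRUE,
                           engine = getOption("enzrxn.engine", "cpp")) {
  if (identical(engine, "cpp")) {
    return(transformer_fb_cpp(model$params, unclass(model$config),
                              batch$src, batch$tgt_in, batch$tgt_out,
                              batch$tgt_mask, batch$src_len, batch$tgt_len,
                              batch$B, batch$Ls, batch$Lt,
                              model$pos[seq_len(max(batch$Ls, batch$Lt)), ,
                                        drop = FALSE],
                              want_grads = grads, train = train))
  }
  p <- model$params; cfg <- model$config
  d <- cfg$model_dim; h <- cfg$heads; nl <- cfg$layers
  dp <- if (train) cfg$dropout else 0
  B <- batch$B; Ls <- batch$Ls; Lt <- batch$Lt
  caches <- list(); masks <- list()
  dmul <- function(X, key) {
    m <- drop_mask(nrow(X), ncol(X), dp)
    masks[[key]] <<- m
    if (is.null(m)) X else X * m
  }

  ## encoder
  X <- dmul(embed_rows(model, batch$src, Ls, B), "Eenc")
  for (l in seq_len(nl)) {
    pn <- function(x) paste0("enc", l, "_", x)
    ln1 <- ln_f(X, p[[pn("ln1g")]], p[[pn("ln1b")]])
    at <- mha_f(ln1$y, ln1$y, p[[pn("Wq")]], p[[pn("Wk")]], p[[pn("Wv")]],
                p[[pn("Wo")]], h, B, Ls, Ls, batch$src_len, causal = FALSE)
    X <- X + dmul(at$out, pn("d1"))
    ln3 <- ln_f(X, p[[pn("ln3g")]], p[[pn("ln3b")]])
    ff <- ffn_f(ln3$y, p[[pn("W1")]], p[[pn("b1")]], p[[pn("W2")]], p[[pn("b2")]])
    X <- X + dmul(ff$out, pn("d2"))
    caches[[pn("ln1")]] <- ln1; caches[[pn("at")]] <- at
    caches[[pn("ln3")]] <- ln3; caches[[pn("ff")]] <- ff
  }
  lnE <- ln_f(X, p$lnEg, p$lnEb)
  mem <- lnE$y
  caches$lnE <- lnE

  ## decoder
  Y <- dmul(embed_rows(model, batch$tgt_in, Lt, B), "Edec")
  for (l in seq_len(nl)) {
    pn <- function(x) paste0("dec", l, "_", x)
    ln1 <- ln_f(Y, p[[pn("ln1g")]], p[[pn("ln1b")]])
    at <- mha_f(ln1$y, ln1$y, p[[pn("Wq")]], p[[pn("Wk")]], p[[pn("Wv")]],
                p[[pn("Wo")]], h, B, Lt, Lt, batch$tgt_len, causal = TRUE)
    Y <- Y + dmul(at$out, pn("d1"))
    ln2 <- ln_f(Y, p[[pn("ln2g")]], p[[pn("ln2b")]])
    ca <- mha_f(ln2$y, mem, p[[pn("cWq")]], p[[pn("cWk")]], p[[pn("cWv")]],
                p[[pn("cWo")]], h, B, Lt, Ls, batch$src_len, causal = FALSE)
    Y <- Y + dmul(ca$out, pn("d2"))
    ln3 <- ln_f(Y, p[[pn("ln3g")]], p[[pn("ln3b")]])
    ff <- ffn_f(ln3$y, p[[pn("W1")]], p[[pn("b1")]], p[[pn("W2")]], p[[pn("b2")]])
    Y <- Y + dmul(ff$out, pn("d3"))
    caches[[pn("ln1")]] <- ln1; caches[[pn("at")]] <- at
    caches[[pn("ln2")]] <- ln2; caches[[pn("ca")]] <- ca
    caches[[pn("ln3")]] <- ln3; caches[[pn("ff")]] <- ff
  }
  lnD <- ln_f(Y, p$lnDg, p$lnDb)
  logits <- lnD$y %*% p$Wout + cbv(p$bout, nrow(lnD$y))

  ## loss (masked mean CE, optional label smoothing)
  mask <- batch$tgt_mask
  nmask <- sum(mask)
  mx <- row_max(logits)
  ex <- exp(logits - mx)
  Z <- rowSums(ex)
  sm <- ex / Z
  tgt_idx <- cbind(seq_len(nrow(logits)), batch$tgt_out)
  nll <- -log(pmax(sm[tgt_idx], 1e-12))
  ls <- cfg$label_smoothing
  V <- model$vocab_size
  if (ls > 0) {
    uni <- -rowMeans(log(pmax(sm, 1e-12)))
    loss <- sum(((1 - ls) * nll + ls * uni)[mask]) / nmask
  } else {
    loss <- sum(nll[mask]) / nmask
  }
  acc <- sum((max.col(logits, ties.method = "first") == batch$tgt_out)[mask]) / nmask
  if (!grads) return(list(loss = loss, acc = acc, n_tokens = nmask))

  g <- list()
  dlogits <- sm
  dlogits[tgt_idx] <- dlogits[tgt_idx] - (1 - ls)
  if (ls > 0) dlogits <- dlogits - ls / V
  dlogits[!mask, ] <- 0
  dlogits <- dlogits / nmask
  g$Wout <- crossprod(lnD$y, dlogits)
  g$bout <- colSums(dlogits)
  dY <- tcrossprod(dlogits, p$Wout)
  lb <- ln_b(dY, lnD, p$lnDg)
  g$lnDg <- lb$dg; g$lnDb <- lb$db
  dY <- lb$dx
  dmem <- matrix(0, nrow(mem), d)
  dback <- function(dX, key) {
    m <- masks[[key]]
    if (is.null(m)) dX else dX * m
  }

  for (l in rev(seq_len(nl))) {
    pn <- function(x) paste0("dec", l, "_", x)
    ff <- caches[[pn("ff")]]
    fb <- ffn_b(dback(dY, pn("d3")), ff, p[[pn("W1")]], p[[pn("W2")]])
    g[[pn("W1")]] <- fb$dW1; g[[pn("b1")]] <- fb$db1
    g[[pn("W2")]] <- fb$dW2; g[[pn("b2")]] <- fb$db2
    lb <- ln_b(fb$dX, caches[[pn("ln3")]], p[[pn("ln3g")]])
    g[[pn("ln3g")]] <- lb$dg; g[[pn("ln3b")]] <- lb$db
    dY <- dY + lb$dx
    cb <- mha_b(dback(dY, pn("d2")), caches[[pn("ca")]],
                p[[pn("cWq")]], p[[pn("cWk")]], p[[pn("cWv")]], p[[pn("cWo")]])
    g[[pn("cWq")]] <- cb$dWq; g[[pn("cWk")]] <- cb$dWk
    g[[pn("cWv")]] <- cb$dWv; g[[pn("cWo")]] <- cb$dWo
    dmem <- dmem + cb$dXkv
    lb <- ln_b(cb$dXq, caches[[pn("ln2")]], p[[pn("ln2g")]])
    g[[pn("ln2g")]] <- lb$dg; g[[pn("ln2b")]] <- lb$db
    dY <- dY + lb$dx
    ab <- mha_b(dback(dY, pn("d1")), caches[[pn("at")]],
                p[[pn("Wq")]], p[[pn("Wk")]], p[[pn("Wv")]], p[[pn("Wo")]])
    g[[pn("Wq")]] <- ab$dWq; g[[pn("Wk")]] <- ab$dWk
    g[[pn("Wv")]] <- ab$dWv; g[[pn("Wo")]] <- ab$dWo
    lb <- ln_b(ab$dXq + ab$dXkv, caches[[pn("ln1")]], p[[pn("ln1g")]])
    g[[pn("ln1g")]] <- lb$dg; g[[pn("ln1b")]] <- lb$db
    dY <- dY + lb$dx
  }
  dEdec <- dback(dY, "Edec") * sqrt(d)

  ## encoder backward
  lb <- ln_b(dmem, caches$lnE, p$lnEg)
  g$lnEg <- lb$dg; g$lnEb <- lb$db
  dX <- lb$dx
  for (l in rev(seq_len(nl))) {
    pn <- function(x) paste0("enc", l, "_", x)
    fb <- ffn_b(dback(dX, pn("d2")), caches[[pn("ff")]],
                p[[pn("W1")]], p[[pn("W2")]])
    g[[pn("W1")]] <- fb$dW1; g[[pn("b1")]] <- fb$db1
    g[[pn("W2")]] <- fb$dW2; g[[pn("b2")]] <- fb$db2
    lb <- ln_b(fb$dX, caches[[pn("ln3")]], p[[pn("ln3g")]])
    g[[pn("ln3g")]] <- lb$dg; g[[pn("ln3b")]] <- lb$db
    dX <- dX + lb$dx
    ab <- mha_b(dback(dX, pn("d1")), caches[[pn("at")]],
                p[[pn("Wq")]], p[[pn("Wk")]], p[[pn("Wv")]], p[[pn("Wo")]])
    g[[pn("Wq")]] <- ab$dWq; g[[pn("Wk")]] <- ab$dWk
    g[[pn("Wv")]] <- ab$dWv; g[[pn("Wo")]] <- ab$dWo
    lb <- ln_b(ab$dXq + ab$dXkv, caches[[pn("ln1")]], p[[pn("ln1g")]])
    g[[pn("ln1g")]] <- lb$dg; g[[pn("ln1b")]] <- lb$db
    dX <- dX + lb$dx
  }
  dEenc <- dback(dX, "Eenc") * sqrt(d)

  ## embedding gradient (shared by encoder and decoder)
  dE <- matrix(0, model$vocab_size, d)
  for (side in list(list(dEenc, batch$src), list(dEdec, batch$tgt_in))) {
    rs <- rowsum(side[[1]], group = side[[2]])
    ids <- as.integer(rownames(rs))
    dE[ids, ] <- dE[ids, ] + rs
  }
  ## padding rows never contribute to the loss
  dE[1, ] <- 0
  g$E <- dE
  list(loss = loss, acc = acc, n_tokens = nmask, grads = g)
}
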
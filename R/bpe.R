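## Byte-pair-encoding tokenizer for enzyme description sentences. Classic
## word-internal BPE: words are split into characters plus an end-of-word
## marker, and the most frequent adjacent symbol pair is merged greedily until
## the target vocabulary size is reached or no pair occurs at least twice.
## Ties between equally frequent pairs break lexicographically on the merged
## string, which makes training deterministic.

.EOW <- "</w>"
.UNK <- "<unk>"

norm_text <- function(x) {
  x <- tolower(trimws(x))
  gsub("\\s+", " ", x)
}

split_words <- function(sentences) {
  w <- unlist(strsplit(norm_text(sentences), " ", fixed = TRUE), use.names = FALSE)
  w[nzchar(w)]
}

word_symbols <- function(word) c(strsplit(word, "", fixed = TRUE)[[1]], .EOW)

pair_counts <- function(syms, wfreq) {
  keys <- character(0); wts <- numeric(0)
  for (i in seq_along(syms)) {
    s <- syms[[i]]
    if (length(s) < 2) next
    k <- paste(s[-length(s)], s[-1], sep = "\u0001")
    keys <- c(keys, k)
    wts <- c(wts, rep(wfreq[i], length(k)))
  }
  if (!length(keys)) return(numeric(0))
  tot <- rowsum(wts, keys)
  stats::setNames(as.numeric(tot), rownames(tot))
}

apply_merge <- function(s, a, b, ab) {
  repeat {
    hit <- which(s[-length(s)] == a & s[-1] == b)
    if (!length(hit)) return(s)
    i <- hit[1]
    s <- c(s[seq_len(i - 1)], ab, s[-seq_len(i + 1)])
  }
}

#' Train a byte-pair-encoding text tokenizer
#'
#' Learns BPE merges over lowercased, whitespace-split words until the
#' vocabulary (base characters plus merged tokens) reaches `target_vocab` or
#' no adjacent symbol pair occurs at least twice. Per-token occurrence
#' frequencies over the training corpus are recorded for later vocabulary
#' truncation.
#'
#' @param sentences character vector of training sentences (at least one
#'   non-empty).
#' @param target_vocab maximum vocabulary size to grow to.
#' @return an object of class `text_tokenizer` with elements `merges`
#'   (two-column character matrix, in merge order), `vocab`, `freq`
#'   (occurrence counts aligned with `vocab`), `max_vocab` and `coverage`.
#' @export
train_bpe <- function(sentences, target_vocab = 3000) {
  words <- split_words(sentences)
  if (!length(words)) stop("train_bpe: empty corpus")
  wtab <- table(words)
  uw <- names(wtab)
  wfreq <- as.numeric(wtab)
  syms <- lapply(uw, word_symbols)
  vocab <- unique(unlist(syms, use.names = FALSE))
  merges <- matrix(character(0), ncol = 2)
  while (length(vocab) < target_vocab) {
    pc <- pair_counts(syms, wfreq)
    if (!length(pc) || max(pc) < 2) break
    best <- names(pc)[pc == max(pc)]
    parts <- strsplit(best, "\u0001", fixed = TRUE)
    merged <- vapply(parts, paste, character(1), collapse = "")
    pick <- order(merged)[1]
    a <- parts[[pick]][1]; b <- parts[[pick]][2]; ab <- merged[pick]
    has <- vapply(syms, function(s) any(s[-length(s)] == a & s[-1] == b), logical(1))
    syms[has] <- lapply(syms[has], apply_merge, a = a, b = b, ab = ab)
    merges <- rbind(merges, c(a, b))
    vocab <- c(vocab, ab)
  }
  ## occurrence frequencies of the final encoding of the training corpus
  freq <- stats::setNames(numeric(length(vocab)), vocab)
  for (i in seq_along(syms)) {
    for (t in syms[[i]]) freq[t] <- freq[t] + wfreq[i]
  }
  structure(list(merges = merges, vocab = vocab, freq = freq,
                 max_vocab = length(vocab), coverage = 1.0),
            class = "text_tokenizer")
}

#' Truncate a BPE vocabulary to its k most frequent tokens
#'
#' Keeps the `k` tokens with the highest training-corpus occurrence counts
#' (ties broken lexicographically) and records the achieved coverage, i.e. the
#' fraction of training-corpus token occurrences still representable. Encoding
#' afterwards maps dropped tokens to the unknown token.
#'
#' @param tok a `text_tokenizer`.
#' @param k number of tokens to retain (>= 1).
#' @return the truncated `text_tokenizer`; `k` at or above the current
#'   vocabulary size is a no-op with coverage 1.
#' @export
truncate_vocab <- function(tok, k) {
  stopifnot(inherits(tok, "text_tokenizer"), k >= 1)
  if (k >= length(tok$vocab)) {
    tok$max_vocab <- length(tok$vocab)
    tok$coverage <- 1.0
    return(tok)
  }
  ord <- order(-tok$freq, names(tok$freq))
  keep <- names(tok$freq)[ord[seq_len(k)]]
  tot <- sum(tok$freq)
  tok$coverage <- if (tot > 0) sum(tok$freq[keep]) / tot else 1.0
  tok$vocab <- keep
  tok$freq <- tok$freq[keep]
  tok$max_vocab <- k
  tok
}

## Encode one word (character vector cache keyed by word).
bpe_encode_word <- function(tok, word, cache = NULL) {
  if (!is.null(cache) && !is.null(cache[[word]])) return(cache[[word]])
  s <- word_symbols(word)
  if (nrow(tok$merges)) {
    for (i in seq_len(nrow(tok$merges))) {
      a <- tok$merges[i, 1]; b <- tok$merges[i, 2]
      if (any(s[-length(s)] == a & s[-1] == b)) {
        s <- apply_merge(s, a, b, paste0(a, b))
      }
    }
  }
  s[!(s %in% tok$vocab)] <- .UNK
  if (!is.null(cache)) cache[[word]] <- s
  s
}

#' Encode text with a trained BPE tokenizer
#'
#' Lowercases, splits on whitespace and applies the learned merges in order.
#' Tokens outside the (possibly truncated) vocabulary become `<unk>`.
#'
#' @param tok a `text_tokenizer`.
#' @param text a single sentence (may be empty).
#' @param cache optional environment used to memoize per-word encodings.
#' @return character vector of BPE tokens (empty for empty text).
#' @export
bpe_encode <- function(tok, text, cache = NULL) {
  words <- split_words(text)
  if (!length(words)) return(character(0))
  unlist(lapply(words, function(w) bpe_encode_word(tok, w, cache)),
         use.names = FALSE)
}

#' Decode BPE tokens back to text
#'
#' @param tokens character vector of BPE tokens.
#' @return single string with word boundaries restored.
#' @export
bpe_decode <- function(tokens) {
  s <- paste(tokens, collapse = "")
  trimws(gsub(.EOW, " ", s, fixed = TRUE))
}
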
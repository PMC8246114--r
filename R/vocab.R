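## Combined vocabulary: atomic SMILES tokens and BPE text tokens share one id
## space (as with a shared-vocabulary preprocessing step), with reserved
## special tokens. SMILES and text tokens live in disjoint id ranges even if
## they render identically, so there are no id collisions between segments.

.SPECIALS <- c(PAD = "<pad>", BOS = "<s>", EOS = "</s>", UNK = "<unk>",
               SEP = "<sep>")

#' Build the combined SMILES + text tokenizer pair
#'
#' @param smiles_vocab character vector of atomic SMILES tokens (see
#'   [build_smiles_vocab()]).
#' @param text_tok a trained (optionally truncated) `text_tokenizer`, or
#'   `NULL` for a SMILES-only model.
#' @return a `tokenizer_pair` with the id table and special-token ids.
#' @export
tokenizer_pair <- function(smiles_vocab, text_tok = NULL) {
  text_vocab <- if (is.null(text_tok)) character(0) else text_tok$vocab
  tokens <- c(unname(.SPECIALS), smiles_vocab, text_vocab)
  segment <- c(rep("special", length(.SPECIALS)),
               rep("smiles", length(smiles_vocab)),
               rep("text", length(text_vocab)))
  pair <- list(tokens = tokens, segment = segment,
               smiles_vocab = smiles_vocab, text_tok = text_tok,
               pad = 1L, bos = 2L, eos = 3L, unk = 4L, sep = 5L,
               smiles_offset = length(.SPECIALS),
               text_offset = length(.SPECIALS) + length(smiles_vocab))
  class(pair) <- "tokenizer_pair"
  pair
}

#' @export
print.tokenizer_pair <- function(x, ...) {
  cat("<tokenizer_pair> vocab:", length(x$tokens),
      "(", length(x$smiles_vocab), "SMILES,",
      length(x$tokens) - length(x$smiles_vocab) - 5L, "text, 5 special )\n")
  invisible(x)
}

#' Total combined vocabulary size
#' @param pair a `tokenizer_pair`.
#' @return integer.
#' @export
vocab_size <- function(pair) length(pair$tokens)

smiles_ids <- function(pair, toks, strict = TRUE) {
  ids <- match(toks, pair$smiles_vocab)
  if (anyNA(ids)) {
    if (strict) {
      stop("unknown SMILES token(s): ",
           paste(unique(toks[is.na(ids)]), collapse = " "))
    }
    warning("unknown SMILES token(s) mapped to <unk>: ",
            paste(unique(toks[is.na(ids)]), collapse = " "))
    out <- ids + pair$smiles_offset
    out[is.na(ids)] <- pair$unk
    return(as.integer(out))
  }
  as.integer(ids + pair$smiles_offset)
}

text_ids <- function(pair, toks) {
  ids <- match(toks, pair$text_tok$vocab)
  out <- ids + pair$text_offset
  out[is.na(ids)] <- pair$unk
  as.integer(out)
}

#' Encode the source side of a reaction
#'
#' Produces the integer id sequence `SMILES tokens ++ <sep> ++ BPE(text)`.
#' Mode `no_text` omits the separator and sentence; `ase_only` keeps only the
#' "-ase" words of the sentence before BPE encoding; an empty sentence under
#' `full_sentence` behaves like `no_text`. Text is lowercased before BPE;
#' SMILES case is never touched (it is chemically meaningful).
#'
#' @param pair a `tokenizer_pair`.
#' @param reactants canonical reactants SMILES.
#' @param enzyme_text enzyme sentence (may be empty).
#' @param mode one of `"full_sentence"`, `"ase_only"`, `"no_text"`.
#' @param strict unknown SMILES tokens raise an error (`TRUE`, training) or
#'   map to `<unk>` with a warning (`FALSE`, inference).
#' @param cache optional environment memoizing BPE word encodings.
#' @return integer id vector.
#' @export
encode_source <- function(pair, reactants, enzyme_text = "",
                          mode = c("full_sentence", "ase_only", "no_text"),
                          strict = TRUE, cache = NULL) {
  mode <- match.arg(mode)
  ids <- smiles_ids(pair, tokenize_smiles(reactants), strict = strict)
  if (mode == "no_text" || is.null(pair$text_tok)) return(ids)
  txt <- enzyme_text
  if (mode == "ase_only") {
    txt <- paste(extract_ase_words(enzyme_text)$ase_words, collapse = " ")
  }
  if (!nzchar(trimws(txt))) return(ids)
  c(ids, pair$sep, text_ids(pair, bpe_encode(pair$text_tok, txt, cache)))
}

#' Encode the target (product) side of a reaction
#'
#' @param pair a `tokenizer_pair`.
#' @param products canonical products SMILES.
#' @param strict see [encode_source()].
#' @return integer id vector (no BOS/EOS; the training loop adds them).
#' @export
encode_target <- function(pair, products, strict = TRUE) {
  smiles_ids(pair, tokenize_smiles(products), strict = strict)
}

#' Decode SMILES token ids back to a SMILES string
#'
#' Special tokens are dropped; decoding stops at the first end-of-sequence id.
#'
#' @param pair a `tokenizer_pair`.
#' @param ids integer id vector.
#' @return single SMILES string.
#' @export
decode_smiles_ids <- function(pair, ids) {
  stopids <- which(ids == pair$eos)
  if (length(stopids)) ids <- ids[seq_len(stopids[1] - 1)]
  ids <- ids[ids > length(.SPECIALS)]
  paste(pair$tokens[ids], collapse = "")
}

#' Encode a whole corpus into parallel id sequences
#'
#' @param pair a `tokenizer_pair`.
#' @param corpus a canonicalized `reaction_corpus`.
#' @param mode source-encoding mode, see [encode_source()].
#' @param strict see [encode_source()].
#' @return list with `src` and `tgt` (lists of integer vectors) and `n`.
#' @export
encode_corpus <- function(pair, corpus,
                          mode = c("full_sentence", "ase_only", "no_text"),
                          strict = TRUE) {
  mode <- match.arg(mode)
  cache <- new.env(parent = emptyenv())
  src <- lapply(seq_len(nrow(corpus)), function(i) {
    encode_source(pair, corpus$reactants[i], corpus$enzyme_text[i],
                  mode = mode, strict = strict, cache = cache)
  })
  tgt <- lapply(corpus$products, encode_target, pair = pair, strict = strict)
  list(src = src, tgt = tgt, n = nrow(corpus))
}

#' Save a tokenizer pair as JSON
#'
#' @param pair a `tokenizer_pair`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_tokenizers <- function(pair, path) {
  tt <- pair$text_tok
  obj <- list(
    smiles_vocab = pair$smiles_vocab,
    bpe_merges = if (is.null(tt)) character(0) else
      apply(tt$merges, 1, paste, collapse = " "),
    text_vocab = if (is.null(tt)) character(0) else tt$vocab,
    text_freq = if (is.null(tt)) numeric(0) else unname(tt$freq),
    special_tokens = as.list(.SPECIALS),
    coverage = if (is.null(tt)) 1.0 else tt$coverage)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a tokenizer pair saved with [save_tokenizers()]
#'
#' @param path JSON file.
#' @return a `tokenizer_pair`.
#' @export
load_tokenizers <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tt <- NULL
  if (length(obj$text_vocab)) {
    merges <- if (length(obj$bpe_merges)) {
      do.call(rbind, strsplit(obj$bpe_merges, " ", fixed = TRUE))
    } else matrix(character(0), ncol = 2)
    tt <- structure(list(merges = merges,
                         vocab = obj$text_vocab,
                         freq = stats::setNames(as.numeric(obj$text_freq),
                                                obj$text_vocab),
                         max_vocab = length(obj$text_vocab),
                         coverage = obj$coverage),
                    class = "text_tokenizer")
  }
  tokenizer_pair(obj$smiles_vocab, tt)
}
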
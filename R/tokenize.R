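## Atomic SMILES tokenization. Every character is its own token except the
## two-letter halogens (Cl, Br), bracketed atom strings ("[C@@H]", "[nH]", ...)
## and %NN two-digit ring-bond numbers, which each form a single token.

.smiles_token_re <- paste0(
  "(\\[[^][]+\\]|Br?|Cl?|N|O|S|P|F|I|b|c|n|o|s|p|",
  "\\(|\\)|\\.|=|#|-|\\+|\\\\|/|:|~|@|\\?|>|\\*|\\$|%[0-9]{2}|[0-9])")

#' Tokenize a SMILES string into atomic tokens
#'
#' Splits a SMILES string into the atomic-token alphabet used for reaction
#' SMILES: single characters, except `Cl`/`Br`, square-bracketed atoms and
#' `%NN` ring-bond labels, which are kept whole. Concatenating the returned
#' tokens reproduces the input exactly.
#'
#' @param s a single SMILES string.
#' @return character vector of tokens.
#' @export
tokenize_smiles <- function(s) {
  stopifnot(is.character(s), length(s) == 1, nzchar(s))
  m <- gregexpr(.smiles_token_re, s, perl = TRUE)[[1]]
  toks <- regmatches(s, list(m))[[1]]
  if (paste(toks, collapse = "") != s) {
    stop("tokenize_smiles: untokenizable SMILES (unbalanced bracket or ",
         "illegal character): ", s)
  }
  toks
}

## Vectorized form: list of token vectors, with the same exactness check.
tokenize_smiles_many <- function(ss) {
  ms <- gregexpr(.smiles_token_re, ss, perl = TRUE)
  toks <- regmatches(ss, ms)
  joined <- vapply(toks, paste, character(1), collapse = "")
  bad <- joined != ss
  if (any(bad)) {
    stop("tokenize_smiles: untokenizable SMILES: ",
         paste(utils::head(ss[bad], 5), collapse = ", "))
  }
  toks
}

#' Reassemble a SMILES string from atomic tokens
#'
#' Inverse of [tokenize_smiles()]: plain concatenation.
#'
#' @param tokens character vector of atomic tokens.
#' @return single SMILES string.
#' @export
detokenize_smiles <- function(tokens) paste(tokens, collapse = "")

.atom_letters <- c("B", "C", "N", "O", "S", "P", "F", "I",
                   "b", "c", "n", "o", "s", "p", "Br", "Cl")

## Heavy-atom count of a single-molecule SMILES (atom tokens only).
n_heavy_atoms <- function(s) {
  t <- tokenize_smiles(s)
  sum(startsWith(t, "[") | t %in% .atom_letters)
}

#' Collect the atomic-token vocabulary of a set of SMILES strings
#'
#' @param smiles character vector of SMILES strings.
#' @return sorted character vector of unique atomic tokens.
#' @export
build_smiles_vocab <- function(smiles) {
  sort(unique(unlist(tokenize_smiles_many(smiles), use.names = FALSE)))
}
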
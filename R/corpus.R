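## Reaction corpus container: one row per enzyme-annotated reaction record
## (reactants SMILES, products SMILES, free-text enzyme sentence, provenance
## id), stored as a data.frame with class "reaction_corpus".

.SEP_TOKEN <- "<sep>"

#' Construct a reaction corpus
#'
#' @param reactants,products character vectors of SMILES (dot-separated for
#'   multi-molecule fields).
#' @param enzyme_text free-text enzyme sentences (may be empty strings).
#'   Newlines/tabs are reserved as field separators and are collapsed to
#'   single spaces.
#' @param source_id optional provenance ids; generated when missing.
#' @param name corpus identifier.
#' @return a `reaction_corpus` (data.frame with columns `reactants`,
#'   `products`, `enzyme_text`, `source_id`).
#' @export
reaction_corpus <- function(reactants, products, enzyme_text = "",
                            source_id = NULL, name = "corpus") {
  n <- length(reactants)
  stopifnot(length(products) == n)
  enzyme_text <- rep_len(as.character(enzyme_text), n)
  enzyme_text <- gsub("[\t\n\r]+", " ", enzyme_text)
  enzyme_text <- trimws(gsub("  +", " ", enzyme_text))
  if (is.null(source_id)) source_id <- sprintf("r%06d", seq_len(n))
  df <- data.frame(reactants = as.character(reactants),
                   products = as.character(products),
                   enzyme_text = enzyme_text,
                   source_id = as.character(source_id),
                   stringsAsFactors = FALSE)
  structure(df, name = name, class = c("reaction_corpus", "data.frame"))
}

as_corpus <- function(df, name = "corpus") {
  reaction_corpus(df$reactants, df$products, df$enzyme_text, df$source_id,
                  name = name)
}

#' @export
print.reaction_corpus <- function(x, ...) {
  cat("<reaction_corpus '", attr(x, "name"), "': ", nrow(x), " records>\n",
      sep = "")
  if (nrow(x)) print(utils::head(as.data.frame(x), 5))
  invisible(x)
}

#' Canonicalize and validate a reaction corpus
#'
#' Canonicalizes reactant and product SMILES (sorting dot-separated
#' components); records whose reactants or products fail to parse are dropped
#' with a reported count, mirroring the removal of reactions lacking either
#' side during dataset curation.
#'
#' @param corpus a `reaction_corpus`.
#' @param quiet suppress the dropped-record message.
#' @return the curated corpus.
#' @export
curate_corpus <- function(corpus, quiet = FALSE) {
  r <- canonicalize_smiles(corpus$reactants, strict = FALSE)
  p <- canonicalize_smiles(corpus$products, strict = FALSE)
  bad <- is.na(r) | is.na(p)
  if (any(bad) && !quiet) {
    message("curate_corpus: dropped ", sum(bad),
            " record(s) with unparsable SMILES")
  }
  out <- corpus[!bad, , drop = FALSE]
  out$reactants <- r[!bad]
  out$products <- p[!bad]
  structure(out, name = attr(corpus, "name"),
            class = c("reaction_corpus", "data.frame"))
}

dedup_key <- function(corpus) {
  paste(corpus$reactants, corpus$products, norm_text(corpus$enzyme_text),
        sep = "\t")
}

#' Remove duplicate reaction records
#'
#' Two records are duplicates when they share canonical reactants, canonical
#' products and the normalized (lowercased, whitespace-collapsed) enzyme
#' sentence. The first occurrence is kept; order is stable. Records equal in
#' reaction SMILES but differing in enzyme description are both retained.
#'
#' @param corpus a canonicalized `reaction_corpus`.
#' @return the deduplicated corpus.
#' @export
deduplicate <- function(corpus) {
  keep <- !duplicated(dedup_key(corpus))
  structure(corpus[keep, , drop = FALSE], name = attr(corpus, "name"),
            class = c("reaction_corpus", "data.frame"))
}

#' Read a reaction corpus from disk
#'
#' Two formats are supported. `tabular`: a UTF-8 TSV with header
#' `reactants  products  enzyme_text  source_id`. `parallel`: OpenNMT-style
#' pre-tokenized source/target files `<path>.src.txt` / `<path>.tgt.txt`, one
#' space-separated line per record, with the reserved `<sep>` token dividing
#' SMILES tokens from enzyme-sentence words on the source side.
#'
#' @param path file path (tabular) or file prefix (parallel).
#' @param format `"tabular"` or `"parallel"`.
#' @param name corpus identifier; defaults to the file base name.
#' @return a `reaction_corpus`.
#' @export
read_corpus <- function(path, format = c("tabular", "parallel"), name = NULL) {
  format <- match.arg(format)
  if (is.null(name)) name <- sub("\\.tsv$", "", basename(path))
  if (format == "tabular") {
    lines <- readLines(path, encoding = "UTF-8")
    if (!length(lines)) stop("read_corpus: empty file: ", path)
    header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    want <- c("reactants", "products", "enzyme_text", "source_id")
    if (!identical(header, want)) {
      stop("read_corpus: bad header in ", path, " (line 1)")
    }
    fields <- strsplit(lines[-1], "\t", fixed = TRUE)
    nf <- lengths(fields)
    ## a trailing empty enzyme_text/source_id field is not emitted by strsplit
    bad <- which(nf < 2 | nf > 4)
    if (length(bad)) {
      stop("read_corpus: malformed line ", bad[1] + 1, " in ", path)
    }
    fields <- lapply(fields, function(f) c(f, rep("", 4 - length(f))))
    m <- do.call(rbind, fields)
    ids <- m[, 4]
    if (any(!nzchar(ids))) ids <- NULL
    return(reaction_corpus(m[, 1], m[, 2], m[, 3],
                           source_id = ids, name = name))
  }
  src <- readLines(paste0(path, ".src.txt"), encoding = "UTF-8")
  tgt <- readLines(paste0(path, ".tgt.txt"), encoding = "UTF-8")
  if (length(src) != length(tgt)) {
    stop("read_corpus: src/tgt length mismatch (", length(src), " vs ",
         length(tgt), ")")
  }
  parse_src <- function(line) {
    toks <- strsplit(line, " ", fixed = TRUE)[[1]]
    cut <- match(.SEP_TOKEN, toks)
    if (is.na(cut)) {
      c(paste(toks, collapse = ""), "")
    } else {
      c(paste(toks[seq_len(cut - 1)], collapse = ""),
        paste(toks[-seq_len(cut)], collapse = " "))
    }
  }
  sm <- t(vapply(src, parse_src, character(2), USE.NAMES = FALSE))
  prods <- vapply(strsplit(tgt, " ", fixed = TRUE), paste, character(1),
                  collapse = "")
  reaction_corpus(sm[, 1], prods, sm[, 2], name = basename(path))
}

#' Write a reaction corpus to disk
#'
#' See [read_corpus()] for the formats. The parallel format tokenizes SMILES
#' with the atomic tokenizer and writes enzyme sentences as whitespace words
#' after the `<sep>` token (records with empty sentences get SMILES tokens
#' only). A write/read round trip reproduces the records.
#'
#' @param corpus a `reaction_corpus`.
#' @param path output path (tabular) or prefix (parallel).
#' @param format `"tabular"` or `"parallel"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("tabular", "parallel")) {
  format <- match.arg(format)
  if (format == "tabular") {
    lines <- c(paste(c("reactants", "products", "enzyme_text", "source_id"),
                     collapse = "\t"),
               paste(corpus$reactants, corpus$products, corpus$enzyme_text,
                     corpus$source_id, sep = "\t"))
    writeLines(lines, path, useBytes = TRUE)
    return(invisible(path))
  }
  rt <- tokenize_smiles_many(corpus$reactants)
  src <- vapply(seq_len(nrow(corpus)), function(i) {
    s <- paste(rt[[i]], collapse = " ")
    txt <- corpus$enzyme_text[i]
    if (nzchar(txt)) paste(s, .SEP_TOKEN, txt) else s
  }, character(1))
  tgt <- vapply(tokenize_smiles_many(corpus$products), paste, character(1),
                collapse = " ")
  writeLines(src, paste0(path, ".src.txt"), useBytes = TRUE)
  writeLines(tgt, paste0(path, ".tgt.txt"), useBytes = TRUE)
  invisible(path)
}
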
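## Dataset analytics and split construction: "-ase"-word extraction,
## enantioselectivity flagging, product-grouped splitting, non-canonical
## augmentation and ablation-set sentence scrambling.

#' Extract enzyme-name ("-ase") words from an enzyme sentence
#'
#' Enzyme names are the whitespace-delimited words whose lowercased,
#' punctuation-stripped form ends in "ase". A minimum word length of 5
#' excludes plain-English words such as "case" or "base" while keeping the
#' shortest real enzyme names ("lyase"). Occurrences are counted, not unique
#' names, so a coupled-enzyme sentence naming two dehydrogenases counts 2.
#'
#' @param sentence a single sentence (may be empty).
#' @return a list with `ase_words` (lowercased, in sentence order),
#'   `ase_count`, and `combination_key` (sorted unique words joined by `+`,
#'   invariant to word order).
#' @export
extract_ase_words <- function(sentence) {
  words <- split_words(sentence)
  words <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", words)
  ase <- words[nchar(words) >= 5 & grepl("ase$", words)]
  list(ase_words = ase,
       ase_count = length(ase),
       combination_key = paste(sort(unique(ase)), collapse = "+"))
}

## Vectorized profile over a corpus: data.frame(ase_count, combination_key).
ase_profiles <- function(sentences) {
  prof <- lapply(sentences, extract_ase_words)
  data.frame(ase_count = vapply(prof, `[[`, integer(1), "ase_count"),
             combination_key = vapply(prof, `[[`, character(1),
                                      "combination_key"),
             stringsAsFactors = FALSE)
}

#' Flag enantioselective / kinetic-resolution reactions
#'
#' A reaction is flagged when its reactants SMILES contains no "@" stereo
#' annotation (no chiral centre, or undefined configuration) while its
#' products SMILES contains at least one, i.e. the enzyme sets the absolute
#' configuration.
#'
#' @param corpus a canonicalized `reaction_corpus` (or a data.frame with
#'   `reactants` and `products` columns).
#' @return logical vector, one flag per record.
#' @export
flag_enantioselective <- function(corpus) {
  !grepl("@", corpus$reactants, fixed = TRUE) &
    grepl("@", corpus$products, fixed = TRUE)
}

#' Split a corpus into train/valid/test with product grouping
#'
#' Records sharing the same canonical product string always land in the same
#' split, so no product that must be predicted at validation/test time has
#' been seen during training. Groups are shuffled with the seed, then
#' assigned greedily (largest group first) to whichever split is furthest
#' below its target record count.
#'
#' @param corpus a deduplicated `reaction_corpus`.
#' @param fractions numeric length-3 vector `(train, valid, test)`, summing
#'   to 1.
#' @param seed integer seed.
#' @return a `split_assignment`: list with `assignment` (factor
#'   train/valid/test per record), `fractions`, `achieved`, `seed`.
#' @export
split_by_product <- function(corpus, fractions = c(0.8, 0.1, 0.1), seed = 42) {
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-8)
  splits <- c("train", "valid", "test")
  groups <- split(seq_len(nrow(corpus)), corpus$products)
  if (length(groups) < 3) stop("split_by_product: fewer than 3 product groups")
  ord <- with_seed(seed, sample.int(length(groups)))
  groups <- groups[ord]
  groups <- groups[order(-lengths(groups))]   # stable: keeps shuffled order in ties
  n <- nrow(corpus)
  target <- fractions * n
  filled <- c(train = 0, valid = 0, test = 0)
  assign <- character(n)
  for (g in groups) {
    deficit <- (target - filled) / pmax(target, 1e-9)
    pick <- splits[which.max(deficit)]
    assign[g] <- pick
    filled[pick] <- filled[pick] + length(g)
  }
  structure(list(assignment = factor(assign, levels = splits),
                 fractions = stats::setNames(fractions, splits),
                 achieved = stats::setNames(as.numeric(filled / n), splits),
                 seed = seed),
            class = "split_assignment")
}

#' @export
print.split_assignment <- function(x, ...) {
  cat("<split_assignment> records:", length(x$assignment), "\n")
  print(round(x$achieved, 4))
  invisible(x)
}

## Convenience: subset a corpus by split label.
corpus_split <- function(corpus, sa, which) {
  structure(corpus[sa$assignment == which, , drop = FALSE],
            name = paste0(attr(corpus, "name"), ".", which),
            class = c("reaction_corpus", "data.frame"))
}

#' Augment a training corpus with non-canonical precursor SMILES
#'
#' Adds, for every record, a duplicate whose reactants are a randomized
#' (non-canonical) SMILES rendering of the same molecules; products and
#' enzyme sentence are unchanged. Doubles the corpus size.
#'
#' @param corpus a `reaction_corpus` (training split).
#' @param seed integer seed for the randomized renderings.
#' @return corpus of twice the size; augmented records carry source ids with
#'   an `-aug` suffix.
#' @export
augment_noncanonical <- function(corpus, seed = 42) {
  aug <- corpus
  aug$reactants <- randomize_smiles(corpus$reactants, seed = seed)
  aug$source_id <- paste0(corpus$source_id, "-aug")
  out <- rbind(as.data.frame(corpus), as.data.frame(aug))
  structure(out, name = attr(corpus, "name"),
            class = c("reaction_corpus", "data.frame"))
}

#' Scramble enzyme sentences between reactions
#'
#' Permutes the `enzyme_text` column with a derangement-preferring shuffle:
#' no record keeps its own sentence unless duplicate sentences force it.
#' Reaction SMILES are untouched and the multiset of sentences is conserved.
#' This builds the ablation test set probing whether the model uses the
#' actual enzyme information rather than the mere presence of text.
#'
#' @param corpus a `reaction_corpus` with at least 2 records.
#' @param seed integer seed.
#' @return the corpus with permuted sentences.
#' @export
scramble_sentences <- function(corpus, seed = 42) {
  n <- nrow(corpus)
  if (n < 2) stop("scramble_sentences: need at least 2 records")
  p <- with_seed(seed, sample.int(n))
  fp <- which(p == seq_len(n))
  if (length(fp) == 1) {
    j <- if (fp == 1) 2L else 1L
    tmp <- p[fp]; p[fp] <- p[j]; p[j] <- tmp
  } else if (length(fp) > 1) {
    p[fp] <- p[c(fp[-1], fp[1])]
  }
  corpus$enzyme_text <- corpus$enzyme_text[p]
  corpus
}

#' Tabulate "-ase" word combinations and counts over a corpus
#'
#' @param corpus a `reaction_corpus`.
#' @return list with `combination` (data.frame `combination_key`, `n`) and
#'   `count` (data.frame `ase_count`, `n`), both sorted by descending `n`;
#'   each table's `n` sums to the corpus size.
#' @export
ase_frequency_table <- function(corpus) {
  prof <- ase_profiles(corpus$enzyme_text)
  comb <- as.data.frame(table(prof$combination_key), stringsAsFactors = FALSE)
  names(comb) <- c("combination_key", "n")
  comb <- comb[order(-comb$n, comb$combination_key), , drop = FALSE]
  cnt <- as.data.frame(table(prof$ase_count), stringsAsFactors = FALSE)
  names(cnt) <- c("ase_count", "n")
  cnt$ase_count <- as.integer(cnt$ase_count)
  cnt <- cnt[order(-cnt$n, cnt$ase_count), , drop = FALSE]
  rownames(comb) <- rownames(cnt) <- NULL
  list(combination = comb, count = cnt)
}
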
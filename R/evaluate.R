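## Scoring predicted products against references: exact and stereo-agnostic
## canonical matches, top-k accuracy, invalid-SMILES rates, strata reports
## and confidence calibration.

#' Compare a predicted product against the reference
#'
#' With `stereo = TRUE` the comparison is canonical-string equality
#' (multi-molecule products compared as sorted dot-joined canonical sets).
#' With `stereo = FALSE` both sides are stripped of stereo annotations and
#' re-canonicalized before comparison. An unparsable hypothesis never
#' matches and is flagged invalid.
#'
#' @param hypothesis predicted SMILES (character vector).
#' @param reference canonical reference SMILES (recycled if length 1).
#' @param stereo require exact stereochemistry.
#' @return data.frame with `match` and `valid` logical columns.
#' @export
match_product <- function(hypothesis, reference, stereo = TRUE) {
  n <- length(hypothesis)
  reference <- rep_len(reference, n)
  can <- rep(NA_character_, n)
  nz <- nzchar(hypothesis)
  can[nz] <- canonicalize_smiles(hypothesis[nz], strict = FALSE)
  valid <- !is.na(can)
  if (stereo) {
    match <- valid & can == reference
  } else {
    m <- rep(FALSE, n)
    if (any(valid)) {
      hs <- canonicalize_smiles(strip_stereo(can[valid]), strict = FALSE)
      rs <- canonicalize_smiles(strip_stereo(reference[valid]), strict = FALSE)
      m[valid] <- !is.na(hs) & !is.na(rs) & hs == rs
    }
    match <- m
  }
  match[is.na(match)] <- FALSE
  data.frame(match = match, valid = valid)
}

#' Score decoded hypotheses against reference products
#'
#' @param pred data.frame of hypotheses with columns `source_index`, `rank`,
#'   `smiles`, `log_prob`, `confidence` (see [decode_to_smiles()]).
#' @param reference character vector of canonical reference products indexed
#'   by `source_index`.
#' @return an `evaluation_report`: headline top-1/top-2 accuracies (stereo-
#'   exact and stereo-agnostic), per-hypothesis invalid rates, a
#'   per-hypothesis table and a per-record table carrying the top-1
#'   confidence.
#' @export
evaluate_predictions <- function(pred, reference) {
  stopifnot(all(c("source_index", "rank", "smiles", "confidence") %in%
                  names(pred)))
  ref <- reference[pred$source_index]
  ex <- match_product(pred$smiles, ref, stereo = TRUE)
  ns <- match_product(pred$smiles, ref, stereo = FALSE)
  hyps <- data.frame(source_index = pred$source_index, rank = pred$rank,
                     smiles = pred$smiles, log_prob = pred$log_prob,
                     confidence = pred$confidence,
                     valid = ex$valid, match = ex$match,
                     match_nostereo = ns$match)
  recs <- sort(unique(hyps$source_index))
  per <- data.frame(source_index = recs)
  agg <- function(k, col) {
    v <- vapply(recs, function(r) {
      h <- hyps[hyps$source_index == r & hyps$rank <= k, col]
      any(h)
    }, logical(1))
    v
  }
  per$top1 <- agg(1, "match")
  per$top2 <- agg(2, "match")
  per$top1_nostereo <- agg(1, "match_nostereo")
  per$top2_nostereo <- agg(2, "match_nostereo")
  c1 <- hyps$confidence[hyps$rank == 1]
  per$confidence <- c1[match(per$source_index,
                             hyps$source_index[hyps$rank == 1])]
  structure(list(
    n = nrow(per),
    top1 = mean(per$top1), top2 = mean(per$top2),
    top1_nostereo = mean(per$top1_nostereo),
    top2_nostereo = mean(per$top2_nostereo),
    invalid1 = mean(!hyps$valid[hyps$rank <= 1]),
    invalid2 = mean(!hyps$valid[hyps$rank <= 2]),
    per_record = per, hyps = hyps), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(paste0("<evaluation_report> n=%d  top1 %.1f%%  top2 %.1f%%  ",
                     "invalid1 %.1f%%  invalid2 %.1f%%\n"),
              x$n, 100 * x$top1, 100 * x$top2, 100 * x$invalid1,
              100 * x$invalid2))
  invisible(x)
}

#' Top-k accuracy and invalid-SMILES rate
#'
#' Accuracy is the fraction of records with a stereo-exact match among the
#' first `k` hypotheses; the invalid rate is the fraction of the `k * N`
#' emitted SMILES that fail to parse (per-hypothesis denominator).
#'
#' @param report an `evaluation_report`.
#' @param k 1 or 2.
#' @return list with `accuracy` and `invalid_rate`.
#' @export
top_k_metrics <- function(report, k) {
  stopifnot(inherits(report, "evaluation_report"), k >= 1)
  cnt <- table(report$hyps$source_index)
  if (any(cnt < k)) stop("top_k_metrics: some records have fewer than ",
                         k, " hypotheses")
  acc <- if (k == 1) report$top1 else if (k == 2) report$top2 else
    mean(vapply(split(report$hyps, report$hyps$source_index),
                function(h) any(h$match[h$rank <= k]), logical(1)))
  list(accuracy = acc,
       invalid_rate = mean(!report$hyps$valid[report$hyps$rank <= k]))
}

#' Stratified evaluation reports
#'
#' Splits the per-record results into disjoint strata: by the number of
#' "-ase" words in the sentence (`ase_count`); by how often the record's
#' "-ase" combination occurs in the training corpus
#' (`combination_frequency`, buckets 0 / 1-5 / 6-20 / 21-100 / >100); the
#' lipase-only subset (`lipase_only`); or the enantioselective subset
#' (`enantioselective_only`).
#'
#' @param report an `evaluation_report`.
#' @param corpus the evaluated `reaction_corpus`, aligned with
#'   `report$per_record$source_index` (row numbers index the corpus).
#' @param by stratification mode.
#' @param train_corpus training `reaction_corpus`, required for
#'   `combination_frequency`.
#' @param breaks upper bucket edges for the frequency mode.
#' @return data.frame with one row per stratum: `stratum`, `n`, `top1`,
#'   `top2`, `top1_nostereo`.
#' @export
stratify <- function(report, corpus,
                     by = c("ase_count", "combination_frequency",
                            "lipase_only", "enantioselective_only"),
                     train_corpus = NULL, breaks = c(0, 5, 20, 100)) {
  by <- match.arg(by)
  per <- report$per_record
  prof <- ase_profiles(corpus$enzyme_text[per$source_index])
  lab <- switch(by,
    ase_count = as.character(prof$ase_count),
    combination_frequency = {
      if (is.null(train_corpus)) {
        stop("stratify: combination_frequency needs train_corpus")
      }
      tt <- table(ase_profiles(train_corpus$enzyme_text)$combination_key)
      f <- as.numeric(tt[prof$combination_key])
      f[is.na(f)] <- 0
      edges <- c(breaks, Inf)
      names <- c("0", paste0(utils::head(breaks, -1) + 1, "-",
                             breaks[-1]), paste0(">", breaks[length(breaks)]))
      idx <- findInterval(f, c(-Inf, breaks + 0.5))
      names[idx]
    },
    lipase_only = {
      has <- vapply(corpus$enzyme_text[per$source_index], function(s) {
        "lipase" %in% extract_ase_words(s)$ase_words
      }, logical(1), USE.NAMES = FALSE)
      ifelse(has, "lipase", "other")
    },
    enantioselective_only = {
      fl <- flag_enantioselective(corpus[per$source_index, , drop = FALSE])
      ifelse(fl, "enantioselective", "other")
    })
  out <- do.call(rbind, lapply(split(seq_len(nrow(per)), lab), function(i) {
    data.frame(n = length(i), top1 = mean(per$top1[i]),
               top2 = mean(per$top2[i]),
               top1_nostereo = mean(per$top1_nostereo[i]))
  }))
  out <- cbind(stratum = rownames(out), out)
  rownames(out) <- NULL
  out
}

#' Confidence calibration table
#'
#' Equal-frequency (quantile) binning of top-1 confidences: records are
#' ordered by confidence and cut into `n_bins` bins whose sizes differ by at
#' most one (exactly equal when `n_bins` divides the record count). Per bin
#' the count, confidence range and fraction of stereo-exact correct top-1
#' predictions are reported, together with the two headline threshold
#' summaries (fraction correct above confidence 0.98; fraction incorrect
#' below 0.80).
#'
#' @param report an `evaluation_report`.
#' @param n_bins number of bins (<= number of records).
#' @return list with `bins` (data.frame), `frac_true_above_98`,
#'   `frac_false_below_80`.
#' @export
calibration_bins <- function(report, n_bins = 5) {
  per <- report$per_record
  n <- nrow(per)
  if (n_bins > n) stop("calibration_bins: more bins than records")
  ord <- order(per$confidence)
  sizes <- rep(n %/% n_bins, n_bins)
  extra <- n %% n_bins
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  bin <- rep(seq_len(n_bins), times = sizes)
  df <- per[ord, ]
  bins <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    i <- which(bin == b)
    data.frame(bin = b, n = length(i),
               conf_lo = min(df$confidence[i]),
               conf_hi = max(df$confidence[i]),
               true_fraction = mean(df$top1[i]))
  }))
  hi <- per$confidence > 0.98
  lo <- per$confidence < 0.80
  list(bins = bins,
       frac_true_above_98 = if (any(hi)) mean(per$top1[hi]) else NA_real_,
       frac_false_below_80 = if (any(lo)) mean(!per$top1[lo]) else NA_real_)
}

#' Decode sources to SMILES hypotheses
#'
#' Runs the beam decoder and maps hypothesis ids back to SMILES strings.
#'
#' @param model an `enz_transformer`.
#' @param pair the `tokenizer_pair`.
#' @param sources list of encoded source id sequences.
#' @param ... passed to [decode_transformer()].
#' @return data.frame with `source_index`, `rank`, `smiles`, `log_prob`,
#'   `confidence`.
#' @export
decode_to_smiles <- function(model, pair, sources, ...) {
  dec <- decode_transformer(model, sources, ...)
  dec$smiles <- vapply(dec$ids, function(ids) decode_smiles_ids(pair, ids),
                       character(1))
  dec$ids <- NULL
  dec
}
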
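## End-to-end experiment orchestration: generate the benchmark, fit
## tokenizers, train the requested (source-mode x regime) cells, evaluate on
## the matched and scrambled test sets and assemble a comparison table.

#' Save / load a model checkpoint
#'
#' The checkpoint carries the tokenizer state (as its JSON serialization) so
#' inference is self-contained.
#'
#' @param model an `enz_transformer`.
#' @param pair the `tokenizer_pair` used to encode its training data.
#' @param path output file.
#' @return `path` (save) or a list `model`, `pair` (load).
#' @export
save_model <- function(model, pair, path) {
  tmp <- tempfile(fileext = ".json")
  save_tokenizers(pair, tmp)
  obj <- list(params = model$params, config = unclass(model$config),
              vocab_size = model$vocab_size,
              tokenizer_json = readChar(tmp, file.size(tmp)))
  unlink(tmp)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  cfg <- do.call(model_config, obj$config[c("layers", "model_dim", "heads",
                                            "ff_dim", "dropout",
                                            "label_smoothing", "max_len")])
  model <- structure(list(params = obj$params, config = cfg,
                          vocab_size = obj$vocab_size,
                          pos = sinusoid_pos(cfg$max_len, cfg$model_dim)),
                     class = "enz_transformer")
  tmp <- tempfile(fileext = ".json")
  writeLines(obj$tokenizer_json, tmp)
  pair <- load_tokenizers(tmp)
  unlink(tmp)
  list(model = model, pair = pair)
}

#' Prepare the benchmark data and tokenizers
#'
#' Generates both synthetic corpora, builds the splits, trains the BPE text
#' tokenizer on the enzymatic training sentences (with top-k truncation) and
#' assembles the shared-vocabulary tokenizer pair.
#'
#' @param gconfig a [generator_config()].
#' @param bpe_target BPE vocabulary grown during training.
#' @param text_vocab truncation size of the text vocabulary.
#' @return list with the suite, split corpora, and `pair`.
#' @export
prepare_benchmark <- function(gconfig = generator_config(),
                              bpe_target = 500, text_vocab = 300) {
  suite <- benchmark_suite(gconfig)
  enz <- suite$enzymatic$corpus
  sa <- suite$enzymatic$split
  gen <- suite$general$corpus
  ga <- suite$general$split
  parts <- list(
    enz_train = corpus_split(enz, sa, "train"),
    enz_valid = corpus_split(enz, sa, "valid"),
    enz_test = corpus_split(enz, sa, "test"),
    gen_train = structure(gen[ga == "train", , drop = FALSE],
                          name = "general.train",
                          class = c("reaction_corpus", "data.frame")),
    gen_valid = structure(gen[ga == "valid", , drop = FALSE],
                          name = "general.valid",
                          class = c("reaction_corpus", "data.frame")))
  smiles_vocab <- build_smiles_vocab(c(enz$reactants, enz$products,
                                       gen$reactants, gen$products))
  tt <- train_bpe(parts$enz_train$enzyme_text, target_vocab = bpe_target)
  tt <- truncate_vocab(tt, text_vocab)
  pair <- tokenizer_pair(smiles_vocab, tt)
  c(list(suite = suite, pair = pair), parts)
}

#' Train one (source-mode, regime) cell on a prepared benchmark
#'
#' @param prep output of [prepare_benchmark()].
#' @param mode source-encoding mode (see [encode_source()]).
#' @param regime training regime (see [train_transformer()]).
#' @param config a [model_config()].
#' @param schedule a [training_schedule()].
#' @param mtl_weights integer weights (specialized, general) for MTL.
#' @param validate monitor the enzymatic validation split during training
#'   (enables accuracy-based checkpoint selection); `FALSE` trains for the
#'   full step budget and keeps the final parameters.
#' @param quiet suppress progress messages.
#' @return the [train_transformer()] result.
#' @export
train_cell <- function(prep, mode, regime, config, schedule,
                       mtl_weights = c(1L, 9L), validate = TRUE,
                       quiet = TRUE) {
  pair <- prep$pair
  enz_tr <- encode_corpus(pair, prep$enz_train, mode = mode)
  valid <- if (validate) encode_corpus(pair, prep$enz_valid, mode = mode)
  data <- switch(regime,
    single = enz_tr,
    mtl = multitask_mixture(
      list(enzr = enz_tr,
           general = encode_corpus(pair, prep$gen_train, mode = mode)),
      weights = mtl_weights),
    stl = list(general = encode_corpus(pair, prep$gen_train, mode = mode),
               specialized = enz_tr))
  train_transformer(config, schedule, data, regime, valid = valid,
                    vocab_size = vocab_size(pair), quiet = quiet)
}

#' Decode and score a test corpus with a trained model
#'
#' @param model an `enz_transformer`.
#' @param pair the `tokenizer_pair`.
#' @param test_corpus the `reaction_corpus` to evaluate.
#' @param mode source-encoding mode used at training time.
#' @param beam_width,n_best,max_len beam-search settings.
#' @return an `evaluation_report`.
#' @export
evaluate_cell <- function(model, pair, test_corpus, mode,
                          beam_width = 2L, n_best = 2L, max_len = 44L) {
  src <- lapply(seq_len(nrow(test_corpus)), function(i) {
    encode_source(pair, test_corpus$reactants[i], test_corpus$enzyme_text[i],
                  mode = mode, strict = FALSE)
  })
  pred <- decode_to_smiles(model, pair, src, beam_width = beam_width,
                           n_best = n_best, max_len = max_len)
  evaluate_predictions(pred, test_corpus$products)
}

#' Run a full model-comparison experiment
#'
#' Trains and evaluates the requested cells of the (source mode x training
#' regime) matrix on the synthetic benchmark, mirroring the published
#' comparison: specialized-only and transfer-learned models, with or without
#' the enzyme sentence, plus the scrambled-sentence ablation of the best
#' full-sentence model.
#'
#' @param cells data.frame with columns `entry`, `mode`, `regime` (defaults
#'   to entries b, d, h, j).
#' @param gconfig a [generator_config()].
#' @param config a [model_config()].
#' @param schedule a [training_schedule()].
#' @param scrambled evaluate full-sentence cells on the scrambled test set
#'   too (ablation entry k).
#' @param out_dir optional directory for corpora, tokenizer, predictions and
#'   the report JSON.
#' @param quiet suppress progress output.
#' @return list with `table` (comparison data.frame), `reports`, `models`
#'   and the prepared benchmark.
#' @export
run_experiment <- function(cells = NULL, gconfig = generator_config(),
                           config = model_config(),
                           schedule = training_schedule(),
                           scrambled = TRUE, out_dir = NULL, quiet = FALSE) {
  if (is.null(cells)) {
    cells <- data.frame(
      entry = c("b", "d", "h", "j"),
      mode = c("no_text", "no_text", "full_sentence", "full_sentence"),
      regime = c("single", "mtl", "single", "mtl"),
      stringsAsFactors = FALSE)
  }
  prep <- prepare_benchmark(gconfig)
  reports <- list(); models <- list()
  tab <- list()
  for (i in seq_len(nrow(cells))) {
    entry <- cells$entry[i]
    if (!quiet) message("training cell (", entry, "): ", cells$mode[i],
                        " / ", cells$regime[i])
    fit <- train_cell(prep, cells$mode[i], cells$regime[i], config, schedule,
                      quiet = quiet)
    rep <- evaluate_cell(fit$model, prep$pair, prep$enz_test, cells$mode[i])
    reports[[entry]] <- rep
    models[[entry]] <- fit
    tab[[length(tab) + 1]] <- data.frame(
      entry = entry, mode = cells$mode[i], regime = cells$regime[i],
      top1 = rep$top1, top2 = rep$top2,
      invalid1 = rep$invalid1, invalid2 = rep$invalid2)
    if (scrambled && cells$mode[i] == "full_sentence" &&
        cells$regime[i] == "mtl") {
      reps <- evaluate_cell(fit$model, prep$pair, prep$suite$test_scrambled,
                            cells$mode[i])
      reports[[paste0(entry, "_scrambled")]] <- reps
      tab[[length(tab) + 1]] <- data.frame(
        entry = "k", mode = "scrambled", regime = cells$regime[i],
        top1 = reps$top1, top2 = reps$top2,
        invalid1 = reps$invalid1, invalid2 = reps$invalid2)
    }
  }
  table <- do.call(rbind, tab)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_corpus(prep$suite$enzymatic$corpus,
                 file.path(out_dir, "enzymatic.tsv"))
    write_corpus(prep$suite$general$corpus, file.path(out_dir, "general.tsv"))
    save_tokenizers(prep$pair, file.path(out_dir, "tokenizers.json"))
    utils::write.table(table, file.path(out_dir, "comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report_json <- lapply(reports, function(r) {
      r[c("n", "top1", "top2", "top1_nostereo", "top2_nostereo",
          "invalid1", "invalid2")]
    })
    manifest <- list(
      generator = unclass(gconfig), model = unclass(config),
      schedule = unclass(schedule),
      corpus_md5 = as.list(tools::md5sum(
        file.path(out_dir, c("enzymatic.tsv", "general.tsv")))))
    jsonlite::write_json(list(reports = report_json, manifest = manifest),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(table = table, reports = reports, models = models, prep = prep)
}

#' Read a run configuration from YAML
#'
#' Accepts the conventional NMT hyperparameter names: `layers`, `rnn_size`
#' (alias for `model_dim`), `word_vec_size` (ignored in favour of the shared
#' model dimension), `heads`, `transformer_ff`, `dropout`,
#' `label_smoothing`, `learning_rate`, `warmup_steps`, `train_steps`,
#' `batch_tokens` (or `batch_size` with `batch_type: tokens`),
#' `accum_count`, `data_weights`, `seed`, plus an optional `generator`
#' section passed to [generator_config()].
#'
#' @param path YAML file.
#' @return list with `config` ([model_config()]), `schedule`
#'   ([training_schedule()]), `gconfig` ([generator_config()]) and
#'   `data_weights`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("read_run_config needs the 'yaml' package")
  }
  y <- yaml::read_yaml(path)
  pick <- function(...) {
    for (nm in c(...)) if (!is.null(y[[nm]])) return(y[[nm]])
    NULL
  }
  dflt <- function(v, d) if (is.null(v)) d else v
  config <- model_config(
    layers = dflt(pick("layers"), 2),
    model_dim = dflt(pick("model_dim", "rnn_size"), 128),
    heads = dflt(pick("heads"), 4),
    ff_dim = dflt(pick("ff_dim", "transformer_ff"), 512),
    dropout = dflt(pick("dropout"), 0.1),
    label_smoothing = dflt(pick("label_smoothing"), 0.0))
  schedule <- training_schedule(
    base_lr = dflt(pick("base_lr", "learning_rate"), 0.6),
    warmup_steps = dflt(pick("warmup_steps"), 250),
    max_steps = dflt(pick("max_steps", "train_steps"), 2000),
    batch_tokens = dflt(pick("batch_tokens", "batch_size"), 1536),
    accum_count = dflt(pick("accum_count"), 1),
    seed = dflt(pick("seed"), 42))
  gconfig <- if (is.null(y$generator)) generator_config(seed = schedule$seed)
             else do.call(generator_config, y$generator)
  list(config = config, schedule = schedule, gconfig = gconfig,
       data_weights = as.integer(dflt(pick("data_weights"), c(1, 9))))
}
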
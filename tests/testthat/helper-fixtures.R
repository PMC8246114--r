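# Shared fixtures. Heavyweight objects are built lazily and memoized so the
# cost is paid once per test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

## A small but structurally complete synthetic enzymatic corpus + manifest.
small_enz <- function() {
  memo("small_enz",
       generate_enzymatic_corpus(generator_config(n_reactions = 400,
                                                  n_general = 800,
                                                  seed = 11)))
}

small_gen <- function() {
  memo("small_gen",
       generate_general_corpus(generator_config(n_reactions = 400,
                                                n_general = 800, seed = 11)))
}

## Hand-built 6-record corpus covering stereo, multi-molecule and empty-text
## cases (already canonical via curate_corpus).
tiny_corpus <- function() {
  memo("tiny_corpus", {
    corp <- reaction_corpus(
      reactants = c("CC(=O)c1ccccc1", "CC(=O)c1ccccc1", "CCO.OC(=O)C",
                    "OCC", "CC(=O)OCC", "c1ccccc1O"),
      products = c("C[C@H](O)c1ccccc1", "C[C@@H](O)c1ccccc1",
                   "CCOC(C)=O", "CC=O", "CCO.CC(=O)O", "Oc1ccc(O)cc1"),
      enzyme_text = c("alcohol dehydrogenase from lactobacillus kefir",
                      "ketoreductase kred-101 from candida magnoliae",
                      "", "choline oxidase", "pig liver esterase",
                      "tyrosinase from agaricus bisporus"),
      name = "tiny")
    curate_corpus(corp, quiet = TRUE)
  })
}

## Fuzzed bracket-heavy SMILES for tokenizer round-trip tests.
fuzz_smiles <- function(n, seed = 1) {
  atoms <- c("C", "c", "N", "O", "S", "Cl", "Br", "F", "I", "[C@H]",
             "[C@@H]", "[nH]", "[N+]", "[O-]", "[13C]", "[Si]", "%12", "(",
             ")", "1", "2", "=", "#", "/", "\\", ".", "-")
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(atoms, sample(3:25, 1), replace = TRUE), collapse = "")
  }, character(1))
}

## Deterministic toy scorer over a 3-token vocabulary {A, B, EOS}: the
## log-probabilities depend on the prefix through a fixed hash, so beam
## search can be checked exactly against brute-force enumeration.
toy_step_fn <- function(vocab_size = 5L) {
  function(prefixes) {
    t(vapply(prefixes, function(ids) {
      h <- sum(ids * seq_along(ids) * 97) %% 1000
      set.seed(h)
      w <- stats::runif(vocab_size)
      w[1:2] <- 0              # never emit pad/bos
      log(w / sum(w))
    }, numeric(vocab_size)))
  }
}

## Brute-force n-best over all sequences up to max_len with the same scorer.
enumerate_best <- function(step_fn, vocab_size, bos = 2L, eos = 3L,
                           max_len = 3L) {
  toks <- setdiff(seq_len(vocab_size), c(1L, bos))
  results <- list()
  rec <- function(prefix, lp) {
    lps <- step_fn(list(prefix))[1, ]
    for (v in toks) {
      if (v == eos) {
        results[[length(results) + 1]] <<-
          list(ids = prefix[-1], lp = lp + lps[v])
      } else if (length(prefix) - 1 < max_len) {
        rec(c(prefix, v), lp + lps[v])
      }
    }
  }
  rec(c(bos), 0)
  lps <- vapply(results, `[[`, numeric(1), "lp")
  ord <- order(-lps)
  list(ids = lapply(results[ord], `[[`, "ids"), lp = lps[ord])
}
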
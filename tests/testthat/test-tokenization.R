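test_that("atomic SMILES tokenization follows the multi-character rules", {
  expect_identical(tokenize_smiles("ClCCBr"), c("Cl", "C", "C", "Br"))
  expect_identical(tokenize_smiles("C[C@@H](O)c1ccccc1"),
                   c("C", "[C@@H]", "(", "O", ")", "c", "1", "c", "c", "c",
                     "c", "c", "1"))
  expect_identical(tokenize_smiles("C%12CC%12"), c("C", "%12", "C", "C", "%12"))
  expect_error(tokenize_smiles("C[C@H(O"), "untokenizable")
  expect_error(tokenize_smiles("C]O["), "untokenizable")
})

test_that("tokenize/detokenize round-trips corpus and fuzzed SMILES", {
  corp <- small_enz()$corpus
  all_smiles <- c(corp$reactants, corp$products, fuzz_smiles(500))
  toks <- enzrxn:::tokenize_smiles_many(all_smiles)
  expect_identical(vapply(toks, detokenize_smiles, character(1)), all_smiles)
})

test_that("BPE training merges the most frequent pair first", {
  tok <- train_bpe(c("abab", "abab"), target_vocab = 300)
  expect_identical(unname(tok$merges[1, ]), c("a", "b"))
  ## token frequency table conserves total occurrences
  enc <- unlist(lapply(c("abab", "abab"), function(s) bpe_encode(tok, s)))
  expect_equal(sum(tok$freq), length(enc))
  ## a single one-character sentence yields base symbols and no merges
  tok1 <- train_bpe("x", target_vocab = 100)
  expect_equal(nrow(tok1$merges), 0)
  expect_setequal(tok1$vocab, c("x", "</w>"))
  expect_error(train_bpe(character(0)), "empty")
  ## determinism: identical corpus -> identical merges
  s <- small_enz()$corpus$enzyme_text[1:200]
  expect_identical(train_bpe(s, 120)$merges, train_bpe(s, 120)$merges)
})

test_that("vocabulary truncation keeps the k most frequent tokens", {
  tok <- structure(list(merges = matrix(character(0), ncol = 2),
                        vocab = c("a", "b", "c"),
                        freq = c(a = 10, b = 5, c = 1),
                        max_vocab = 3, coverage = 1.0),
                   class = "text_tokenizer")
  tr <- truncate_vocab(tok, 2)
  expect_setequal(tr$vocab, c("a", "b"))
  expect_equal(tr$coverage, 15 / 16)
  ## k >= |vocab| is a no-op with coverage 1
  expect_identical(truncate_vocab(tok, 3)$vocab, tok$vocab)
  expect_equal(truncate_vocab(tok, 99)$coverage, 1.0)
  ## dropped tokens encode as <unk>
  tok2 <- train_bpe(c("lipase lipase lipase esterase"), 50)
  tr2 <- truncate_vocab(tok2, 3)
  expect_true("<unk>" %in% bpe_encode(tr2, "esterase"))
})

test_that("coverage is non-decreasing in k", {
  sent <- small_enz()$corpus$enzyme_text
  tok <- train_bpe(sent, 250)
  cov <- vapply(c(5, 20, 50, 100, 200, 250),
                function(k) truncate_vocab(tok, k)$coverage, numeric(1))
  expect_true(all(diff(cov) >= 0))
  expect_equal(cov[length(cov)], 1.0)
})

test_that("combined vocabulary is collision-free and modes encode correctly", {
  corp <- tiny_corpus()
  tt <- train_bpe(corp$enzyme_text[nzchar(corp$enzyme_text)], 80)
  pair <- tokenizer_pair(build_smiles_vocab(c(corp$reactants, corp$products)),
                         tt)
  expect_equal(vocab_size(pair),
               5 + length(pair$smiles_vocab) + length(tt$vocab))
  ## no id collisions across segments
  expect_equal(anyDuplicated(paste(pair$tokens, pair$segment)), 0)

  r <- corp$reactants[1]; txt <- corp$enzyme_text[1]
  no <- encode_source(pair, r, txt, mode = "no_text")
  expect_identical(no, encode_target(pair, r))
  full <- encode_source(pair, r, txt, mode = "full_sentence")
  expect_true(pair$sep %in% full)
  expect_true(all(full >= 1 & full <= vocab_size(pair)))
  ## ase_only keeps only the enzyme-name words
  ase <- encode_source(pair, r, "reduction with alcohol dehydrogenase in buffer",
                       mode = "ase_only")
  cut <- match(pair$sep, ase)
  txt_ids <- ase[-seq_len(cut)]
  expect_identical(txt_ids,
                   enzrxn:::text_ids(pair, bpe_encode(tt, "dehydrogenase")))
  ## empty sentence under full_sentence behaves as no_text
  expect_identical(encode_source(pair, r, "", mode = "full_sentence"), no)
  ## unseen SMILES tokens: error when strict, <unk> + warning otherwise
  expect_error(encode_source(pair, "CCCS", mode = "no_text"), "unknown")
  expect_warning(ids <- encode_source(pair, "CCCS", mode = "no_text",
                                      strict = FALSE), "unk")
  expect_true(pair$unk %in% ids)
})

test_that("tokenizer state survives a JSON save/load round trip", {
  corp <- small_enz()$corpus
  tt <- truncate_vocab(train_bpe(corp$enzyme_text, 200), 150)
  pair <- tokenizer_pair(build_smiles_vocab(corp$reactants), tt)
  f <- tempfile(fileext = ".json")
  save_tokenizers(pair, f)
  back <- load_tokenizers(f)
  expect_identical(back$tokens, pair$tokens)
  expect_identical(back$text_tok$merges, pair$text_tok$merges)
  expect_equal(back$text_tok$coverage, pair$text_tok$coverage)
  s <- corp$enzyme_text[42]
  expect_identical(bpe_encode(back$text_tok, s), bpe_encode(tt, s))
})
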
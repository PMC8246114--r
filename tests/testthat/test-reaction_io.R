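test_that("canonicalization identifies renderings and preserves stereo", {
  expect_identical(canonicalize_smiles("OCC"), canonicalize_smiles("CCO"))
  can <- canonicalize_smiles("C[C@H](O)CC")
  ## exactly one tetrahedral annotation (@ or @@) survives canonicalization
  expect_equal(lengths(regmatches(can, gregexpr("@{1,2}", can)))[[1]], 1)
  ## idempotence
  s <- c("c1ccccc1O", "CC(=O)OC[C@@H](N)C(=O)O", "CCO.CC(=O)O")
  expect_identical(canonicalize_smiles(canonicalize_smiles(s)),
                   canonicalize_smiles(s))
  ## multi-molecule component order never matters
  expect_identical(canonicalize_smiles("CCO.CC(=O)O"),
                   canonicalize_smiles("CC(=O)O.CCO"))
  expect_error(canonicalize_smiles("C1CC"), "parse")
  expect_error(canonicalize_smiles(""), "empty")
  expect_true(is.na(canonicalize_smiles("C1CC", strict = FALSE)))
})

test_that("randomize_smiles permutes atom order but not the molecule", {
  corp <- small_enz()$corpus
  set.seed(3)
  mols <- sample(unique(corp$reactants), 60)
  for (seed in c(1, 2)) {
    rnd <- randomize_smiles(mols, seed = seed)
    expect_identical(canonicalize_smiles(rnd), mols)
  }
  ## determinism
  expect_identical(randomize_smiles(mols, seed = 5),
                   randomize_smiles(mols, seed = 5))
  ## at least one rendering differs from canonical across 50 seeds
  s <- "c1ccccc1O"
  outs <- vapply(1:50, function(k) randomize_smiles(s, k), character(1))
  expect_gt(sum(outs != canonicalize_smiles(s)), 0)
  ## degenerate single-atom input has a single rendering
  expect_identical(randomize_smiles("C", 1), "C")
})

test_that("deduplicate keys on reactants, products and normalized sentence", {
  corp <- reaction_corpus(
    reactants = rep("CCO", 4),
    products = rep("CC=O", 4),
    enzyme_text = c("alcohol dehydrogenase", "Alcohol  Dehydrogenase",
                    "choline oxidase", "alcohol dehydrogenase"))
  corp <- curate_corpus(corp, quiet = TRUE)
  dd <- deduplicate(corp)
  ## case/whitespace-normalized duplicates collapse; different sentences stay
  expect_equal(nrow(dd), 2)
  expect_equal(dd$source_id, c("r000001", "r000003"))
  ## projection property
  expect_identical(as.data.frame(deduplicate(dd)), as.data.frame(dd))
  ## empty corpus passes through
  empty <- corp[0, , drop = FALSE]
  expect_equal(nrow(deduplicate(empty)), 0)
})

test_that("curation drops unparsable records with a message", {
  corp <- reaction_corpus(c("CCO", "C1CC", "CCC"), c("CC=O", "CCO", "xyz"),
                          "")
  expect_message(out <- curate_corpus(corp), "dropped 2")
  expect_equal(nrow(out), 1)
  expect_equal(out$reactants, canonicalize_smiles("CCO"))
})

test_that("tabular corpus round-trips byte-identically", {
  corp <- tiny_corpus()
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  write_corpus(corp, f1)
  back <- read_corpus(f1, name = "tiny")
  expect_identical(as.data.frame(back), as.data.frame(corp))
  write_corpus(back, f2)
  expect_identical(readLines(f1), readLines(f2))
  ## malformed line is reported with its number
  lines <- readLines(f1)
  lines[4] <- "only_one_field"
  writeLines(lines, f2)
  expect_error(read_corpus(f2), "line 4")
})

test_that("parallel corpus round-trips including empty sentences", {
  corp <- small_enz()$corpus[1:100, ]
  corp$enzyme_text[7] <- ""
  corp <- structure(corp, class = c("reaction_corpus", "data.frame"))
  pre <- tempfile()
  write_corpus(corp, pre, format = "parallel")
  src <- readLines(paste0(pre, ".src.txt"))
  expect_length(src, 100)
  ## empty sentence -> SMILES tokens only, no separator
  expect_false(grepl("<sep>", src[7], fixed = TRUE))
  back <- read_corpus(pre, format = "parallel")
  expect_identical(back$reactants, corp$reactants)
  expect_identical(back$products, corp$products)
  expect_identical(tolower(back$enzyme_text), tolower(corp$enzyme_text))
  ## second serialization is byte-identical
  pre2 <- tempfile()
  write_corpus(back, pre2, format = "parallel")
  expect_identical(readLines(paste0(pre, ".src.txt")),
                   readLines(paste0(pre2, ".src.txt")))
  expect_identical(readLines(paste0(pre, ".tgt.txt")),
                   readLines(paste0(pre2, ".tgt.txt")))
  ## src/tgt length mismatch errors
  writeLines(src[-1], paste0(pre, ".src.txt"))
  expect_error(read_corpus(pre, format = "parallel"), "mismatch")
})
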
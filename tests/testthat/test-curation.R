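test_that("-ase word extraction strips punctuation and counts occurrences", {
  p <- extract_ase_words("Candida antarctica lipase B")
  expect_identical(p$ase_words, "lipase")
  expect_equal(p$ase_count, 1)
  expect_equal(extract_ase_words("glucose dehydrogenase alcohol dehydrogenase")$ase_count, 2)
  expect_equal(extract_ase_words("")$ase_count, 0)
  ## short English words ending in -ase are not enzyme names
  expect_equal(extract_ase_words("in any case the base was used")$ase_count, 0)
  expect_identical(extract_ase_words("a lyase,")$ase_words, "lyase")
  ## combination key is order-invariant and deduplicated
  a <- extract_ase_words("lipase and esterase")$combination_key
  b <- extract_ase_words("esterase with lipase lipase")$combination_key
  expect_identical(a, b)
})

test_that("enantioselectivity flag matches the product-only-stereo rule", {
  corp <- data.frame(
    reactants = c("CC(=O)c1ccccc1", "C[C@H](O)CC", "CCO"),
    products = c("C[C@H](O)c1ccccc1", "CC(=O)CC", "CC=O"))
  expect_identical(flag_enantioselective(corp), c(TRUE, FALSE, FALSE))
})

test_that("enantioselectivity flag agrees with a stereocenter-parsing oracle", {
  corp <- small_enz()$corpus[1:150, ]
  flags <- flag_enantioselective(corp)
  ## independent oracle: RDKit's assigned stereocenter enumeration
  script <- paste(
    "import sys, json",
    "from rdkit import Chem",
    "out = []",
    "for line in sys.stdin:",
    "    r, p = line.rstrip('\\n').split('\\t')",
    "    nr = len(Chem.FindMolChiralCenters(Chem.MolFromSmiles(r), useLegacyImplementation=False))",
    "    np = len(Chem.FindMolChiralCenters(Chem.MolFromSmiles(p), useLegacyImplementation=False))",
    "    out.append(nr == 0 and np > 0)",
    "print(json.dumps(out))", sep = "\n")
  f <- tempfile(fileext = ".py"); writeLines(script, f)
  inp <- tempfile(); writeLines(paste(corp$reactants, corp$products, sep = "\t"), inp)
  res <- suppressWarnings(
    system2("python", f, stdout = TRUE, stderr = FALSE, stdin = inp))
  expect_gt(length(res), 0)
  oracle <- unlist(jsonlite::fromJSON(res[length(res)]))
  expect_identical(flags, oracle)
})

test_that("product-grouped splits never leak products and hit the fractions", {
  enz <- small_enz()$corpus
  sa <- split_by_product(enz, c(0.8, 0.1, 0.1), seed = 42)
  for (pairing in list(c("train", "valid"), c("train", "test"),
                       c("valid", "test"))) {
    a <- enz$products[sa$assignment == pairing[1]]
    b <- enz$products[sa$assignment == pairing[2]]
    expect_length(intersect(a, b), 0)
  }
  expect_true(all(abs(sa$achieved - c(0.8, 0.1, 0.1)) < 0.05))
  ## determinism
  sb <- split_by_product(enz, c(0.8, 0.1, 0.1), seed = 42)
  expect_identical(sa$assignment, sb$assignment)
  ## each product group lands wholly in one split
  g <- split(as.character(sa$assignment), enz$products)
  expect_true(all(vapply(g, function(x) length(unique(x)) == 1, logical(1))))
  expect_error(split_by_product(enz[enz$products == enz$products[1], ],
                                c(0.8, 0.1, 0.1), 1), "fewer than 3")
})

test_that("augmentation doubles the corpus without changing the chemistry", {
  corp <- small_enz()$corpus[1:50, ]
  aug <- augment_noncanonical(corp, seed = 4)
  expect_equal(nrow(aug), 100)
  expect_identical(canonicalize_smiles(aug$reactants[51:100]),
                   corp$reactants)
  expect_identical(aug$products[51:100], corp$products)
  expect_identical(aug$enzyme_text[51:100], corp$enzyme_text)
  ## single record degenerate case
  one <- augment_noncanonical(corp[1, , drop = FALSE], seed = 1)
  expect_equal(nrow(one), 2)
  expect_identical(canonicalize_smiles(one$reactants[2]), one$reactants[1])
})

test_that("sentence scrambling is a conservation-preserving derangement", {
  corp <- tiny_corpus()[1:2, ]
  sc <- scramble_sentences(corp, seed = 1)
  expect_identical(sc$enzyme_text, corp$enzyme_text[c(2, 1)])
  big <- small_enz()$corpus
  big <- big[!duplicated(big$enzyme_text), ]   # distinct sentences
  fp <- vapply(1:20, function(seed) {
    sc <- scramble_sentences(big, seed)
    mean(sc$enzyme_text == big$enzyme_text)
  }, numeric(1))
  expect_lt(mean(fp), 0.01)
  sc <- scramble_sentences(big, 3)
  expect_identical(sort(sc$enzyme_text), sort(big$enzyme_text))
  expect_identical(sc$reactants, big$reactants)
  expect_error(scramble_sentences(big[1, ], 1), "at least 2")
})

test_that("ase frequency tables partition the corpus", {
  corp <- reaction_corpus(
    rep("CCO", 5), rep("CC=O", 5),
    c("lipase", "lipase", "alcohol dehydrogenase", "esterase", "no enzyme"))
  tab <- ase_frequency_table(corp)
  expect_equal(sum(tab$count$n), 5)
  expect_equal(sum(tab$combination$n), 5)
  expect_equal(tab$count$n[tab$count$ase_count == 1], 4)
  expect_equal(tab$combination$combination_key[1], "lipase")
  ## descending order
  expect_true(all(diff(tab$combination$n) <= 0))
})
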
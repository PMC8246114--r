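test_that("the generator is deterministic and chemically valid", {
  cfg <- generator_config(n_reactions = 300, n_general = 600, seed = 21)
  a <- generate_enzymatic_corpus(cfg)
  b <- generate_enzymatic_corpus(cfg)
  expect_identical(as.data.frame(a$corpus), as.data.frame(b$corpus))
  expect_identical(a$manifest, b$manifest)
  ## every SMILES is valid and canonical (idempotent under canonicalization)
  expect_true(all(smiles_valid(a$corpus$reactants)))
  expect_true(all(smiles_valid(a$corpus$products)))
  expect_identical(canonicalize_smiles(a$corpus$products), a$corpus$products)
  ## records are unique: dedup is a no-op
  expect_equal(nrow(deduplicate(a$corpus)), nrow(a$corpus))
  ## every sentence names at least one enzyme
  expect_true(all(enzrxn:::ase_profiles(a$corpus$enzyme_text)$ase_count >= 1))
})

test_that("manifest stereochemistry matches the emitted products", {
  enz <- small_enz()
  man <- enz$manifest
  corp <- enz$corpus
  has_at <- grepl("@", corp$products, fixed = TRUE)
  expect_identical(has_at, man$stereo != "none")
  expect_identical(man$stereo != "none", man$stereo_informative)
  ## substrates of stereo-informative records carry no stereo annotation
  expect_false(any(grepl("@", corp$reactants[man$stereo_informative],
                         fixed = TRUE)))
  ## enzyme family determines the transformation template
  expect_true(all(tapply(man$template, man$family,
                         function(x) length(unique(x)) == 1)))
})

test_that("stereo-informative substrates are ambiguous without the sentence", {
  enz <- memo("ambig_enz",
              generate_enzymatic_corpus(generator_config(n_reactions = 3000,
                                                         n_general = 1000,
                                                         seed = 33)))
  man <- enz$manifest
  corp <- enz$corpus
  sub <- corp$reactants[man$stereo_informative]
  prod <- corp$products[man$stereo_informative]
  ## for substrates sampled with more than a couple of records, both R and S
  ## products (or different transformation types) must occur, so the best
  ## text-blind guess cannot exceed the majority share
  per_sub <- tapply(prod, sub, function(p) max(table(p)) / length(p))
  counts <- table(sub)
  busy <- names(counts)[counts >= 8]
  expect_true(all(per_sub[busy] <= 0.75))
  ## the R/S split across the whole informative subset is near-balanced
  r_share <- mean(man$stereo[man$stereo_informative] == "R")
  expect_lt(abs(r_share - 0.5), 0.15)
})

test_that("label noise flips the configured fraction of stereo outcomes", {
  base <- generate_enzymatic_corpus(generator_config(n_reactions = 600,
                                                     n_general = 600,
                                                     seed = 13, noise = 0))
  noisy <- generate_enzymatic_corpus(generator_config(n_reactions = 600,
                                                      n_general = 600,
                                                      seed = 13, noise = 0.2))
  differs <- base$corpus$products != noisy$corpus$products
  stereo <- base$manifest$stereo != "none"
  expect_true(all(differs[!stereo] == FALSE))
  expect_gt(mean(differs[stereo]), 0.1)
  expect_lt(mean(differs[stereo]), 0.3)
})

test_that("the general corpus is enzyme-free and shares the SMILES alphabet", {
  gen <- small_gen()
  expect_true(all(gen$enzyme_text == ""))
  expect_equal(sum(enzrxn:::ase_profiles(gen$enzyme_text)$ase_count), 0)
  expect_true(all(smiles_valid(gen$reactants)))
  ## default sizing keeps the general corpus at least 5x the enzymatic one
  cfg <- generator_config()
  expect_gte(cfg$n_general / cfg$n_reactions, 5)
  ## randomized duplicates encode the same reactions
  rnd <- grepl("-rnd$", gen$source_id)
  expect_gt(sum(rnd), 0)
  base <- sub("-rnd$", "", gen$source_id[rnd])
  orig <- gen[match(base, gen$source_id), ]
  expect_identical(canonicalize_smiles(gen$reactants[rnd]), orig$reactants)
  ## the general corpus introduces no tokens outside the shared vocabulary
  enz <- small_enz()$corpus
  vocab <- build_smiles_vocab(c(enz$reactants, enz$products,
                                gen$reactants, gen$products))
  gvoc <- build_smiles_vocab(c(gen$reactants, gen$products))
  expect_true(all(gvoc %in% vocab))
})

test_that("benchmark suite wires splits and the scrambled variant correctly", {
  cfg <- generator_config(n_reactions = 400, n_general = 800, seed = 11)
  suite <- memo("suite400", benchmark_suite(cfg))
  enz <- suite$enzymatic$corpus
  sa <- suite$enzymatic$split
  tr <- enz$products[sa$assignment == "train"]
  te <- enz$products[sa$assignment == "test"]
  expect_length(intersect(tr, te), 0)
  sc <- suite$test_scrambled
  test <- enz[sa$assignment == "test", ]
  expect_identical(sc$reactants, test$reactants)
  expect_identical(sc$products, test$products)
  expect_identical(sort(sc$enzyme_text), sort(test$enzyme_text))
  expect_false(identical(sc$enzyme_text, test$enzyme_text))
  ## enantioselective share tracks the stereo-informative configuration
  frac <- mean(flag_enantioselective(enz))
  expect_lt(abs(frac - cfg$stereo_informative_fraction), 0.05)
})

test_that("an exhausted template pool is reported with the family", {
  expect_error(generate_enzymatic_corpus(
    generator_config(n_reactions = 5000, n_scaffolds = 2, n_variants = 1)),
    "pool exhausted")
})
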
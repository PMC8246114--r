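test_that("product matching is canonical and stereo-aware", {
  ref <- canonicalize_smiles("CCO")
  expect_true(match_product("OCC", ref)$match)
  r <- match_product("C[C@H](O)CC", canonicalize_smiles("C[C@@H](O)CC"),
                     stereo = TRUE)
  expect_false(r$match)
  r2 <- match_product("C[C@H](O)CC", canonicalize_smiles("C[C@@H](O)CC"),
                      stereo = FALSE)
  expect_true(r2$match)
  ## unparsable hypotheses are invalid and never match
  r3 <- match_product("C1CC", ref)
  expect_false(r3$match); expect_false(r3$valid)
  ## multi-molecule products compare as sorted component sets
  expect_true(match_product("CCO.CC(=O)O",
                            canonicalize_smiles("CC(=O)O.CCO"))$match)
})

make_fake_predictions <- function(n, seed = 1) {
  ## synthetic prediction records with known structure: some correct at rank
  ## 1, some at rank 2, some wrong, some invalid
  refs <- canonicalize_smiles(rep(c("CCO", "CC(=O)c1ccccc1", "CCN", "CCCC",
                                    "C[C@H](O)c1ccccc1"), length.out = n))
  set.seed(seed)
  cls <- sample(c("hit1", "hit2", "miss", "invalid"), n, replace = TRUE,
                prob = c(0.45, 0.2, 0.25, 0.1))
  rows <- list()
  for (i in seq_len(n)) {
    wrong <- "c1ccncc1"
    r1 <- switch(cls[i], hit1 = refs[i], hit2 = wrong,
                 miss = wrong, invalid = "C1CC(")
    r2 <- switch(cls[i], hit1 = wrong, hit2 = refs[i],
                 miss = "CCCCCCCCC", invalid = "CCCCCCCCC")
    conf <- stats::runif(1, 0.2, 0.99)
    rows[[i]] <- data.frame(source_index = i, rank = 1:2,
                            smiles = c(r1, r2),
                            log_prob = log(c(conf, conf / 2)),
                            confidence = c(conf, conf / 2))
  }
  list(pred = do.call(rbind, rows), refs = refs, cls = cls)
}

test_that("top-k metrics count exactly what an independent recount counts", {
  fx <- make_fake_predictions(120)
  rep <- evaluate_predictions(fx$pred, fx$refs)
  expect_equal(rep$top1, mean(fx$cls == "hit1"))
  expect_equal(rep$top2, mean(fx$cls %in% c("hit1", "hit2")))
  expect_equal(rep$invalid1, mean(fx$cls == "invalid"))
  expect_equal(rep$invalid2, mean(fx$cls == "invalid") / 2)
  m1 <- top_k_metrics(rep, 1)
  m2 <- top_k_metrics(rep, 2)
  expect_gte(m2$accuracy, m1$accuracy)
  expect_equal(m1$accuracy, rep$top1)
  ## a record counted correct at rank r has a valid hypothesis at rank r
  h <- rep$hyps
  expect_true(all(h$valid[h$match]))
  expect_error(top_k_metrics(
    evaluate_predictions(fx$pred[fx$pred$rank == 1, ], fx$refs), 2),
    "fewer than")
})

test_that("three-record counting example yields top1 1/3 and top2 2/3", {
  refs <- canonicalize_smiles(c("CCO", "CCN", "CCC"))
  pred <- data.frame(
    source_index = rep(1:3, each = 2), rank = rep(1:2, 3),
    smiles = c("OCC", "CCCCO", "c1ccccc1", "NCC", "CCCCN", "CCCCC"),
    log_prob = log(rep(c(0.8, 0.4), 3)),
    confidence = rep(c(0.8, 0.4), 3))
  rep <- evaluate_predictions(pred, refs)
  expect_equal(rep$top1, 1 / 3)
  expect_equal(rep$top2, 2 / 3)
  expect_equal(rep$invalid1, 0)
})

test_that("stratification partitions the records in every mode", {
  enz <- small_enz()
  corp <- enz$corpus
  n <- 80
  ## perfect predictions at rank 1 for a subset; wrong elsewhere
  pred <- do.call(rbind, lapply(seq_len(n), function(i) {
    good <- i %% 3 == 0
    data.frame(source_index = i, rank = 1:2,
               smiles = c(if (good) corp$products[i] else "CCCCCCCC",
                          "CCCCCCC"),
               log_prob = log(c(0.9, 0.3)), confidence = c(0.9, 0.3))
  }))
  rep <- evaluate_predictions(pred, corp$products)
  for (mode in c("ase_count", "lipase_only", "enantioselective_only")) {
    st <- stratify(rep, corp, mode)
    expect_equal(sum(st$n), n)
  }
  st <- stratify(rep, corp, "combination_frequency", train_corpus = corp)
  expect_equal(sum(st$n), n)
  expect_error(stratify(rep, corp, "combination_frequency"), "train_corpus")
  ## the lipase stratum is exactly the records naming a lipase
  stl <- stratify(rep, corp, "lipase_only")
  has_lip <- grepl("lipase", tolower(corp$enzyme_text[seq_len(n)]))
  expect_equal(stl$n[stl$stratum == "lipase"], sum(has_lip))
})

test_that("calibration bins are equal-frequency and threshold summaries work", {
  fx <- make_fake_predictions(100)
  rep <- evaluate_predictions(fx$pred, fx$refs)
  cal <- calibration_bins(rep, 5)
  expect_identical(cal$bins$n, rep(20L, 5))
  ## bins partition and are ordered by confidence
  expect_true(all(diff(cal$bins$conf_lo) >= 0))
  expect_error(calibration_bins(rep, 101), "more bins")
  ## all-correct predictions give true fraction 1 in every bin
  good <- fx$pred
  idx1 <- good$rank == 1
  good$smiles[idx1] <- fx$refs
  good$smiles[!idx1] <- "c1ccncc1"
  repg <- evaluate_predictions(good, fx$refs)
  calg <- calibration_bins(repg, 5)
  expect_true(all(calg$bins$true_fraction == 1))
  expect_equal(calg$frac_true_above_98, if (any(repg$per_record$confidence > 0.98)) 1 else NA_real_)
  expect_equal(calg$frac_false_below_80, 0)
})
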
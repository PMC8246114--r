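## Synthetic enzymatic-reaction generator.
##
## Emulates the statistical structure of a literature-derived biocatalysis
## corpus: substrates drawn from combinatorial scaffold grids, products
## produced by enzyme-family reaction templates (ketone reduction, reductive
## amination, ester hydrolysis, decarboxylation, alcohol oxidation), enzyme
## free-text sentences containing "-ase" words, organism names, strain codes
## and occasional mutation tokens, and a lipase-heavy family skew. For
## stereo-informative substrate classes, paired (R)- and (S)-selective
## enzymes act on the same ketones, so the sentence is the only disambiguator
## of product chirality and a text-blind model cannot exceed 50% stereo-exact
## accuracy on that subset. A companion general-chemistry corpus (ester
## formation, amide coupling, oxidation, halogenation; empty enzyme text)
## supplies transferable chemistry knowledge for MTL/STL regimes.

## Attachable substituent fragments (first written atom is the attachment).
## Kept deliberately compact: short fragments keep source/target sequences
## short, which is what makes desk-scale CPU training of the transformer
## feasible while preserving the combinatorial structure of the task.
.aryl <- c("c1ccccc1", "c1ccc(F)cc1", "c1ccc(Cl)cc1", "c1ccc(Br)cc1",
           "c1ccc(C)cc1", "c1ccc(O)cc1", "c1ccc(OC)cc1", "c1ccc(N)cc1",
           "c1cccc(C)c1", "c1cccc(F)c1", "c1cccc(Cl)c1", "c1ccc(I)cc1")
.aryl_extra <- c("c1ccncc1", "c1cccnc1", "c1ccsc1", "c1ccoc1",
                 "c1ccc(S)cc1", "c1cccc(Br)c1")
.alkyl <- c("C", "CC", "CCC", "CCCC", "C(C)C")
.alkyl_extra <- c("CC(C)C", "CCCCC")

ketone_smiles <- function(alkyl, aryl) paste0("O=C(", alkyl, ")", aryl)
chiral_alcohol <- function(alkyl, aryl, stereo) {
  paste0("O[C@", if (stereo == "S") "@" else "", "H](", alkyl, ")", aryl)
}
chiral_amine <- function(alkyl, aryl, stereo) {
  paste0("N[C@", if (stereo == "S") "@" else "", "H](", alkyl, ")", aryl)
}
ester_smiles <- function(acyl, alc) paste0("O=C(O", alc, ")", acyl)
acid_smiles <- function(acyl) paste0("O=C(O)", acyl)
alcohol_smiles <- function(alc) paste0("O", alc)
amide_smiles <- function(acyl, amine) paste0("O=C(N", amine, ")", acyl)
sec_alcohol <- function(alkyl, aryl) paste0("OC(", alkyl, ")", aryl)

## Enzyme roster. Stereo-capable families (alcohol dehydrogenase,
## ketoreductase, transaminase) act on aryl ketones with a fixed (R)/(S)
## preference; the transaminase triple mutant flips the parent preference,
## exercising mutation sensitivity.
enzyme_roster <- function() {
  e <- function(id, family, stereo, sentence) {
    data.frame(enzyme = id, family = family, stereo = stereo,
               sentence = sentence, stringsAsFactors = FALSE)
  }
  rbind(
    e("adh1", "alcohol dehydrogenase", "R", "alcohol dehydrogenase from lactobacillus kefir"),
    e("adh2", "alcohol dehydrogenase", "S", "alcohol dehydrogenase from rhodococcus ruber dsm 44541"),
    e("adh3", "alcohol dehydrogenase", "R", "nadph dependent alcohol dehydrogenase from thermoanaerobacter brockii"),
    e("adh4", "alcohol dehydrogenase", "S", "glucose dehydrogenase alcohol dehydrogenase ymr226c from saccharomyces cerevisiae"),
    e("adh5", "alcohol dehydrogenase", "S", "alcohol dehydrogenase from sphingobium yanoikuyae"),
    e("kred1", "ketoreductase", "R", "ketoreductase kred-119 from lactobacillus brevis"),
    e("kred2", "ketoreductase", "S", "ketoreductase kred-101 from candida magnoliae"),
    e("kred3", "ketoreductase", "S", "glucose dehydrogenase ketoreductase p2-d11 from sporobolomyces salmonicolor"),
    e("kred4", "ketoreductase", "R", "ketoreductase from pichia glucozyma cbs 5766"),
    e("ta1", "transaminase", "S", "omega-transaminase from chromobacterium violaceum"),
    e("ta2", "transaminase", "R", "omega-transaminase ata-117 from arthrobacter sp"),
    e("ta3", "transaminase", "S", "omega-transaminase ata-117 from arthrobacter sp triple mutant w58l f86a v153a"),
    e("ta4", "transaminase", "S", "amine transaminase from vibrio fluvialis js17"),
    e("lip1", "lipase", "none", "candida antarctica lipase b"),
    e("lip2", "lipase", "none", "lipase from pseudomonas cepacia"),
    e("lip3", "lipase", "none", "porcine pancreatic lipase"),
    e("lip4", "lipase", "none", "lipase from candida rugosa immobilized on celite"),
    e("est1", "esterase", "none", "pig liver esterase"),
    e("est2", "esterase", "none", "carboxylesterase from bacillus subtilis"),
    e("dec1", "decarboxylase", "none", "arylacetate decarboxylase from enterococcus faecium"),
    e("dec2", "decarboxylase", "none", "decarboxylase from pseudomonas putida kt2440"),
    e("oxi1", "oxidase", "none", "choline oxidase from arthrobacter globiformis"),
    e("oxi2", "oxidase", "none", "alcohol oxidase from pichia pastoris"),
    e("oxi3", "oxidase", "none", "galactose oxidase variant m1 from fusarium graminearum")
  )
}

.sentence_suffixes <- c("", " recombinant expressed in escherichia coli",
                        " whole cells", " atcc 33019", " lyophilized powder",
                        " immobilized preparation", " cell free extract")

.stereo_families <- c("alcohol dehydrogenase", "ketoreductase", "transaminase")

## Default family prevalence (single-lipase share ~17%, stereo families 50%).
.family_weights <- c("lipase" = 0.17, "esterase" = 0.07,
                     "alcohol dehydrogenase" = 0.20, "ketoreductase" = 0.15,
                     "transaminase" = 0.15, "decarboxylase" = 0.04,
                     "oxidase" = 0.22)

#' Synthetic-generator configuration
#'
#' Defaults define the desk-scale benchmark: 5000 enzymatic reactions with a
#' lipase-heavy family skew, half of them from stereo-informative substrate
#' classes, and a 25 000-reaction general-chemistry companion corpus.
#'
#' @param n_reactions number of enzymatic reactions.
#' @param n_general number of general-chemistry reactions (counting the
#'   randomized-SMILES duplicate each canonical reaction carries).
#' @param family_weights named prevalence weights over enzyme families.
#' @param stereo_informative_fraction total weight given to the
#'   stereo-informative families (paired R/S enzymes on shared ketones).
#' @param n_enzymes optional cap on the number of enzyme specs used.
#' @param n_scaffolds optional cap on the aryl scaffold grid.
#' @param n_variants sentence variants rendered per enzyme.
#' @param noise label-error rate: fraction of enzymatic records whose product
#'   stereochemistry is flipped (stereo templates) to emulate database-entry
#'   errors.
#' @param seed integer seed.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_reactions = 5000, n_general = 25000,
                             family_weights = NULL,
                             stereo_informative_fraction = 0.5,
                             n_enzymes = NULL, n_scaffolds = NULL,
                             n_variants = 5, noise = 0, seed = 42) {
  fw <- if (is.null(family_weights)) .family_weights else family_weights
  stopifnot(n_reactions >= 1, n_general >= 1, all(fw >= 0),
            stereo_informative_fraction >= 0, stereo_informative_fraction <= 1,
            noise >= 0, noise <= 1)
  ## rescale stereo vs non-stereo family mass to the requested fraction
  st <- names(fw) %in% .stereo_families
  f <- stereo_informative_fraction
  if (sum(fw[st]) > 0) fw[st] <- fw[st] / sum(fw[st]) * f
  if (sum(fw[!st]) > 0) fw[!st] <- fw[!st] / sum(fw[!st]) * (1 - f)
  structure(list(n_reactions = as.integer(n_reactions),
                 n_general = as.integer(n_general),
                 family_weights = fw,
                 stereo_informative_fraction = f,
                 n_enzymes = n_enzymes, n_scaffolds = n_scaffolds,
                 n_variants = as.integer(n_variants),
                 noise = noise, seed = as.integer(seed)),
            class = "generator_config")
}

## Canonicalize a vector of template-built SMILES, memoizing distinct strings.
canon_memo <- function(smiles) {
  u <- unique(smiles)
  cu <- canonicalize_smiles(u)
  cu[match(smiles, u)]
}

## Enumerate the (enzyme, substrate, sentence-variant) pool with weights and
## the template-defined products.
enzymatic_pool <- function(config) {
  roster <- enzyme_roster()
  if (!is.null(config$n_enzymes)) {
    roster <- roster[seq_len(min(nrow(roster), config$n_enzymes)), ]
  }
  aryl <- .aryl
  if (!is.null(config$n_scaffolds)) aryl <- aryl[seq_len(min(length(aryl), config$n_scaffolds))]
  alkyl <- .alkyl
  ketones <- as.matrix(expand.grid(alkyl = alkyl, aryl = aryl,
                                   stringsAsFactors = FALSE))
  acyls <- c("C", "CC", "CCC", "C(C)C")
  leaving <- c(paste0("C", aryl[seq_len(min(10, length(aryl)))]), alkyl)
  esters <- as.matrix(expand.grid(acyl = acyls, alc = leaving,
                                  stringsAsFactors = FALSE))
  acid_frag <- c(paste0("C", aryl), paste0("CC", aryl))
  alcohols <- rbind(cbind(alkyl = ketones[, "alkyl"], aryl = ketones[, "aryl"], kind = "sec"),
                    cbind(alkyl = "", aryl = aryl, kind = "prim"))
  out <- list()
  for (i in seq_len(nrow(roster))) {
    en <- roster[i, ]
    recs <- switch(
      en$family,
      "alcohol dehydrogenase" = ,
      "ketoreductase" = data.frame(
        reactants = ketone_smiles(ketones[, "alkyl"], ketones[, "aryl"]),
        products = chiral_alcohol(ketones[, "alkyl"], ketones[, "aryl"], en$stereo),
        template = "ketone_reduction", stringsAsFactors = FALSE),
      "transaminase" = data.frame(
        reactants = ketone_smiles(ketones[, "alkyl"], ketones[, "aryl"]),
        products = chiral_amine(ketones[, "alkyl"], ketones[, "aryl"], en$stereo),
        template = "reductive_amination", stringsAsFactors = FALSE),
      "lipase" = ,
      "esterase" = data.frame(
        reactants = ester_smiles(esters[, "acyl"], esters[, "alc"]),
        products = paste(acid_smiles(esters[, "acyl"]),
                         alcohol_smiles(esters[, "alc"]), sep = "."),
        template = "ester_hydrolysis", stringsAsFactors = FALSE),
      ## ArCH2COOH -> ArCH3 (the acyl fragment is itself the decarboxylated
      ## hydrocarbon when read as a standalone SMILES)
      "decarboxylase" = data.frame(
        reactants = acid_smiles(acid_frag),
        products = acid_frag,
        template = "decarboxylation", stringsAsFactors = FALSE),
      "oxidase" = data.frame(
        reactants = ifelse(alcohols[, "kind"] == "sec",
                           sec_alcohol(alcohols[, "alkyl"], alcohols[, "aryl"]),
                           paste0("OC", alcohols[, "aryl"])),
        products = ifelse(alcohols[, "kind"] == "sec",
                          ketone_smiles(alcohols[, "alkyl"], alcohols[, "aryl"]),
                          paste0("O=C", alcohols[, "aryl"])),
        template = "alcohol_oxidation", stringsAsFactors = FALSE)
    )
    for (v in seq_len(config$n_variants)) {
      sfx <- .sentence_suffixes[((v - 1) %% length(.sentence_suffixes)) + 1]
      r <- recs
      r$enzyme_text <- paste0(en$sentence, sfx)
      r$enzyme <- en$enzyme
      r$family <- en$family
      r$stereo <- en$stereo
      r$variant <- v
      out[[length(out) + 1]] <- r
    }
  }
  pool <- do.call(rbind, out)
  nf <- table(pool$family)
  pool$weight <- as.numeric(config$family_weights[pool$family] / nf[pool$family])
  pool$stereo_informative <- pool$family %in% .stereo_families
  pool
}

#' Generate the synthetic enzymatic corpus
#'
#' Samples `n_reactions` distinct (enzyme, substrate, sentence-variant)
#' combinations from the template pool, weighted by family prevalence, and
#' returns the canonicalized corpus together with a ground-truth manifest
#' naming the generating enzyme, family, template, stereo outcome and
#' stereo-informative flag of every record.
#'
#' @param config a [generator_config()].
#' @return list with `corpus` (a `reaction_corpus`) and `manifest`
#'   (data.frame aligned by `source_id`).
#' @export
generate_enzymatic_corpus <- function(config = generator_config()) {
  pool <- enzymatic_pool(config)
  n <- config$n_reactions
  if (n > nrow(pool)) {
    short <- names(which.max(table(pool$family)))
    stop("generate_enzymatic_corpus: template/scaffold pool exhausted (",
         nrow(pool), " < ", n, " reactions; largest family ", short, ")")
  }
  idx <- with_seed(config$seed, sample.int(nrow(pool), n, prob = pool$weight))
  rec <- pool[idx, , drop = FALSE]
  if (config$noise > 0) {
    flip <- with_seed(config$seed + 7L,
                      stats::runif(n) < config$noise) & rec$stereo != "none"
    if (any(flip)) {
      swap <- function(s) chartr("RS", "SR", s)
      rec$stereo[flip] <- swap(rec$stereo[flip])
      rec$products[flip] <- ifelse(
        grepl("@@", rec$products[flip], fixed = TRUE),
        sub("@@", "@", rec$products[flip], fixed = TRUE),
        sub("@", "@@", rec$products[flip], fixed = TRUE))
    }
  }
  ids <- sprintf("enz%05d", seq_len(n))
  corpus <- reaction_corpus(canon_memo(rec$reactants), canon_memo(rec$products),
                            rec$enzyme_text, source_id = ids,
                            name = "synthetic-enzymatic")
  manifest <- data.frame(source_id = ids, enzyme = rec$enzyme,
                         family = rec$family, template = rec$template,
                         stereo = rec$stereo,
                         stereo_informative = rec$stereo_informative,
                         variant = rec$variant, stringsAsFactors = FALSE)
  list(corpus = corpus, manifest = manifest)
}

## Enumerate the general-chemistry reaction pool (no enzyme text).
general_pool <- function() {
  aryl <- c(.aryl, .aryl_extra)
  alkyl <- c(.alkyl, .alkyl_extra)
  acyls <- c(paste0("C", aryl), paste0("CC", aryl), aryl, alkyl)
  alcs <- c(paste0("C", aryl),
            as.vector(outer(alkyl, aryl, function(k, a) paste0("C(", k, ")", a))),
            alkyl)
  amines <- c(paste0("C", aryl), aryl, alkyl)
  est <- expand.grid(acyl = acyls, alc = alcs, stringsAsFactors = FALSE)
  ami <- expand.grid(acyl = acyls, amine = amines, stringsAsFactors = FALSE)
  oxs <- expand.grid(alkyl = alkyl, aryl = aryl, stringsAsFactors = FALSE)
  eth <- expand.grid(alkyl = alkyl, alc = alcs, stringsAsFactors = FALSE)
  rbind(
    data.frame(reactants = paste(acid_smiles(est$acyl), alcohol_smiles(est$alc),
                                 sep = "."),
               products = ester_smiles(est$acyl, est$alc),
               template = "esterification", stringsAsFactors = FALSE),
    data.frame(reactants = paste(acid_smiles(ami$acyl), paste0("N", ami$amine),
                                 sep = "."),
               products = amide_smiles(ami$acyl, ami$amine),
               template = "amide_coupling", stringsAsFactors = FALSE),
    data.frame(reactants = sec_alcohol(oxs$alkyl, oxs$aryl),
               products = ketone_smiles(oxs$alkyl, oxs$aryl),
               template = "oxidation", stringsAsFactors = FALSE),
    data.frame(reactants = paste(sec_alcohol(oxs$alkyl, oxs$aryl), "O=S(Cl)Cl",
                                 sep = "."),
               products = paste0("ClC(", oxs$alkyl, ")", oxs$aryl),
               template = "halogenation", stringsAsFactors = FALSE),
    data.frame(reactants = paste(alcohol_smiles(eth$alc),
                                 paste0("Cl", eth$alkyl), sep = "."),
               products = paste0("O(", eth$alkyl, ")", eth$alc),
               template = "ether_formation", stringsAsFactors = FALSE),
    data.frame(reactants = paste(ketone_smiles(oxs$alkyl, oxs$aryl),
                                 "[Na+].[BH4-]", sep = "."),
               products = sec_alcohol(oxs$alkyl, oxs$aryl),
               template = "hydride_reduction", stringsAsFactors = FALSE))
}

#' Generate the general-chemistry companion corpus
#'
#' Non-enzymatic single-step transformations (ester formation, amide
#' coupling, alcohol oxidation, halogenation) over the same scaffold
#' vocabulary, with empty enzyme text. Mirroring the structure of the
#' stereo-augmented patent corpus, each sampled canonical reaction also
#' carries a duplicate with a randomized precursor rendering, so the corpus
#' teaches SMILES variability as well as chemistry.
#'
#' @param config a [generator_config()]; `n_general` counts records including
#'   the randomized duplicates.
#' @return a `reaction_corpus`.
#' @export
generate_general_corpus <- function(config = generator_config()) {
  pool <- general_pool()
  n_can <- ceiling(config$n_general / 2)
  if (n_can > nrow(pool)) {
    stop("generate_general_corpus: pool exhausted (", nrow(pool), " < ",
         n_can, ")")
  }
  idx <- with_seed(config$seed + 1L, sample.int(nrow(pool), n_can))
  rec <- pool[idx, , drop = FALSE]
  can_r <- canon_memo(rec$reactants)
  can_p <- canon_memo(rec$products)
  rnd_r <- randomize_smiles(can_r, seed = config$seed + 2L)
  k <- config$n_general - n_can
  df <- data.frame(
    reactants = c(can_r, rnd_r[seq_len(k)]),
    products = c(can_p, can_p[seq_len(k)]),
    stringsAsFactors = FALSE)
  reaction_corpus(df$reactants, df$products, "",
                  source_id = c(sprintf("gen%05d", seq_len(n_can)),
                                sprintf("gen%05d-rnd", seq_len(k))),
                  name = "synthetic-general")
}

## Random (ungrouped) split helper for the general corpus.
random_split <- function(n, fractions = c(0.9, 0.05, 0.05), seed = 42) {
  lab <- c("train", "valid", "test")
  cut <- floor(cumsum(fractions) * n)
  out <- character(n)
  ord <- with_seed(seed, sample.int(n))
  out[ord[seq_len(cut[1])]] <- "train"
  out[ord[(cut[1] + 1):cut[2]]] <- "valid"
  out[ord[(cut[2] + 1):n]] <- "test"
  factor(out, levels = lab)
}

#' Build the full desk-scale benchmark suite
#'
#' Generates both corpora, product-grouped 80/10/10 splits for the enzymatic
#' corpus, random 90/5/5 splits for the general corpus, and the
#' derangement-scrambled variant of the enzymatic test set (identical
#' reaction SMILES, permuted sentences).
#'
#' @param config a [generator_config()].
#' @return list with `enzymatic` (`corpus`, `manifest`, `split`), `general`
#'   (`corpus`, `split`) and `test_scrambled` (a `reaction_corpus`).
#' @export
benchmark_suite <- function(config = generator_config()) {
  enz <- generate_enzymatic_corpus(config)
  gen <- generate_general_corpus(config)
  sa <- split_by_product(enz$corpus, c(0.8, 0.1, 0.1), seed = config$seed)
  ga <- random_split(nrow(gen), seed = config$seed)
  test <- corpus_split(enz$corpus, sa, "test")
  list(enzymatic = c(enz, list(split = sa)),
       general = list(corpus = gen, split = ga),
       test_scrambled = scramble_sentences(test, seed = config$seed + 3L))
}
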
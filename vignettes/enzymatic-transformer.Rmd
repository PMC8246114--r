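---
title: "Predicting enzymatic reaction products with a text-conditioned transformer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting enzymatic reaction products with a text-conditioned transformer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Biocatalysis replaces harsh chemical reagents with enzymes that carry out
chemo-, regio- and enantioselective transformations under mild conditions.
The hard question for a synthetic chemist is *predictive*: given a substrate
and an enzyme — usually described informally, e.g. "alcohol dehydrogenase
from *Lactobacillus kefir*" — what product, with what stereochemistry, will
form?

`enzrxn` treats this as sequence-to-sequence translation. The source
sequence is the substrate SMILES, tokenized into atomic tokens, optionally
followed by a separator and the free-text enzyme sentence, tokenized by byte
pair encoding (BPE); the target sequence is the product SMILES. A single
encoder–decoder transformer consumes both segments through one shared
vocabulary, so the model learns chemistry and the fragment of natural
language chemists use for enzymes — including organism names, strain codes
and point-mutation tokens — in the same embedding space.

## The model and training regimes

The transformer is the standard pre-norm encoder–decoder: multi-head scaled
dot-product attention, ReLU feed-forward blocks, sinusoidal positional
encodings, shared source/target embeddings, beam-search decoding. It is
implemented in R with hand-written backpropagation over BLAS matrix
operations; a finite-difference gradient check is part of the test suite.
We use pre-norm residual blocks (LayerNorm before each sublayer) rather
than the original post-norm arrangement because pre-norm is markedly more
stable at the short warmups desk-scale training uses.

Three training regimes are provided, because a few thousand enzymatic
reactions are too few to learn chemistry from scratch:

* **single** — train on one corpus only;
* **STL** (sequential transfer learning) — train on the large
  general-chemistry corpus, then continue from those weights on the
  enzymatic corpus (the noam schedule continues across the boundary, so the
  fine-tuning phase starts at a low, stable learning rate);
* **MTL** (multi-task transfer learning) — train on a weighted mixture,
  with a deterministic interleave that takes exactly `w_i` batches from
  corpus `i` per cycle. The reference weighting is 1 (enzymatic) : 9
  (general).

Optimization is Adam (betas 0.9/0.998) under the noam schedule
`lr = base_lr * d^(-1/2) * min(s^(-1/2), s * w^(-3/2))`. Two configurations
are built in: the reference configuration (4 layers, dimension 384, 8
heads, feed-forward 2048, 8000-step warmup, base rate 4, 200 000 steps,
token batches of 6144 with 4-step accumulation) and the desk-scale default
(2 layers, dimension 128, 4 heads, feed-forward 512). Desk-scale training
uses token batches of 1536, 1900 steps, 250-step warmup and base rate 0.6;
the base rate was chosen by an overfitting probe on a 200-record subset —
peak rates above ~5e-3 visibly oscillate at this model size, while ~2e-3
descends monotonically — and the batch size by the observation that, at a
fixed wall-clock budget, fewer steps over larger token batches fit this
task better than more steps over small ones. Dropout is 0.1 in the
reference configuration; the desk-scale experiments set it to 0 because
each example is seen only a couple of times, so regularization only slows
the fit. The compiled training core computes in single precision (the
common choice for neural-network training); the reference R implementation
computes in double precision and doubles as the numerical oracle for the
compiled path in the test suite.

Decoding is n-best beam search with cached decoder self-attention (one
incremental forward step per generated token). A hypothesis's confidence is
the product of its token probabilities, `exp(sum log p)`; this is the
default of a pluggable scorer, since length-normalized variants exist in
the literature and the headline thresholds (0.98 / 0.80) are quoted on the
product scale.

## Data handling

Reaction records are (reactants SMILES, products SMILES, enzyme sentence,
provenance id). Curation canonicalizes all SMILES with Open Babel (the
toolkit-canonical rendering preserves tetrahedral annotations), sorts
dot-separated components so reagent order cannot create spurious uniques,
drops unparsable records with a logged count, and deduplicates on the
triple (canonical reactants, canonical products, normalized sentence) —
the sentence is part of the key, so the same transformation annotated with
two different enzymes is two records. Normalization for the key lowercases
and collapses whitespace; stored text keeps its casing.

Splits are grouped by canonical product string: all records sharing a
product land in the same train/validation/test part, so every evaluated
product is unseen during training. Groups are assigned largest-first to the
part furthest below its target fraction, which hits 80/10/10 tightly even
with skewed group sizes. The training split can be augmented by duplicating
each record with a randomized (rooted-atom) rendering of its precursors.

"-ase" words — whitespace-delimited, punctuation-stripped words of length
at least five ending in "ase" — serve as the coarse enzyme-family label.
The length cutoff excludes English words like "case" and "base" while
keeping "lyase"; occurrences are counted rather than unique names so a
coupled cofactor-regeneration system with two dehydrogenases counts as two.
Enantioselective (kinetic-resolution-like) records are flagged by the
absence of "@" in the reactants and its presence in the products.

## The synthetic benchmark

The licensed enzymatic corpus the original study used cannot be
redistributed, so the package generates a synthetic stand-in whose
*statistical structure* mirrors it. Enzyme specs (24 enzymes in 7 families,
lipase-heavy, with multi-"-ase" cofactor-regeneration sentences and a
stereo-flipping triple-mutant transaminase) apply reaction templates —
ketone reduction, reductive amination, ester hydrolysis, decarboxylation,
alcohol oxidation — to combinatorial scaffold grids of aryl/alkyl
fragments. Half the family prevalence sits in stereo-informative classes:
paired (R)- and (S)-selective enzymes act on the same prochiral ketones, so
the sentence is the only signal disambiguating product chirality and a
text-blind model cannot exceed 50% stereo-exact accuracy on that subset
(in practice it does far worse, because the transformation *type* — alcohol
vs amine — is also sentence-determined). The companion general corpus
(ester formation, amide coupling, oxidation, halogenation, ether formation,
hydride reduction; empty sentences) supplies transferable chemistry.

Default sizes are 5000 enzymatic and 25 000 general reactions. Scaffold
fragments are deliberately short (source sequences average ~25 tokens):
short sequences keep CPU training fast and raise sequence-exact accuracy
for a given token accuracy, without changing the logical structure of the
task. Sentence variants (strain codes, preparation suffixes) expand the
unique-record pool and exercise BPE truncation. An optional label-noise
knob flips the stereo outcome of a configured fraction of records,
emulating database-entry errors; it defaults to 0.

What the generator does *not* emulate: real literature-derived enzyme
descriptions (the vocabulary is template-bounded), multi-step cascades,
cofactor co-substrates as explicit reagents, and the long-tailed substrate
diversity of patent data. Passing
the benchmark therefore demonstrates that the pipeline's machinery —
text-conditioned product prediction, stereochemical control by the
sentence, transfer learning, ablations — behaves directionally like the
full-scale study, not that desk-scale accuracies transfer to real data.

## Evaluation

Predictions are canonicalized and compared as strings; "correct" means an
exact stereo match (stereo-agnostic accuracy is reported alongside).
Top-k accuracy asks whether the reference appears among the first k
hypotheses; the invalid-SMILES rate uses the per-hypothesis denominator
(all k·N emitted strings). Stratifications follow the study's analyses:
by "-ase" count, by training-set frequency of the record's "-ase"
combination (buckets 0 / 1–5 / 6–20 / 21–100 / >100, configurable — the
source only states that more than five examples marks a performance step),
the lipase-only subset and the enantioselective subset. Confidence
calibration uses equal-frequency bins of top-1 confidences plus the two
threshold summaries (fraction of predictions correct above 0.98, fraction
incorrect below 0.80).

## Numerical choices and degenerate inputs

* BPE ties (equal pair counts) break lexicographically on the merged
  string, making training deterministic; vocabulary truncation ties break
  lexicographically too.
* Beam-search ties on log-probability prefer shorter, then
  lexicographically smaller token sequences.
* A randomized rendering falls back to the input rendering for root atoms
  Open Babel refuses; single-atom molecules have exactly one rendering.
* The sentence scrambler prefers derangements; duplicate sentences can
  force fixed points, which is accepted (the multiset is conserved).
* Empty sentences under `full_sentence` encode exactly like `no_text`.
* Unknown SMILES tokens are an error at training time (the chemical
  vocabulary is closed) and map to `<unk>` with a warning at inference.
* Equal-frequency calibration bins differ by at most one record when the
  bin count does not divide the record count.

## Desk-scale problem sizes

The bundled experiments (and the acceptance script) train the desk
configuration for 1900 steps per cell over ~1536-token batches — roughly
two to three epochs of the mixed corpus — and evaluate 100–150 of the ~500
held-out enzymatic test records with beam width 2. Under these conditions the
full-sentence MTL model reaches sequence-exact accuracies far above the
text-blind model, the scrambled-sentence ablation collapses toward the
text-blind level, and calibration is monotone across bins; absolute values
are printed by `scripts/acceptance.R` and in the README's worked example
rather than quoted here.

## Known limitations

* Open Babel's canonical SMILES differs from RDKit's; all comparisons are
  internally consistent but canonical strings are not interchangeable with
  RDKit-canonicalized data.
* The R implementation trains a ~1M-parameter model in minutes on one CPU;
  it is not intended for the reference 200 000-step configuration.
* The two vocabulary-size observables of the original preprocessing
  (405 atomic tokens; 6139-token BPE vocabulary truncated to 3000 at 97.4%
  coverage) are exposed by `build_smiles_vocab()` and `train_bpe()` /
  `truncate_vocab()` but can only be reproduced with the external corpora.
* Retro-synthesis (product-to-substrate) is out of scope.
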
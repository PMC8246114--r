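# enzrxn — enzymatic reaction product prediction with a sequence-to-sequence transformer

`enzrxn` predicts the product of an enzyme-catalysed reaction — including
its stereochemistry — from the substrate SMILES and a *free-text description
of the enzyme* ("alcohol dehydrogenase from *Lactobacillus kefir*",
"*Candida antarctica* lipase B", "omega-transaminase … triple mutant W58L
…"). It is aimed at computational chemists and biocatalysis researchers who
want a fully inspectable, desk-scale implementation of the
text-conditioned molecular-transformer approach to biotransformation
prediction.

The core idea: treat product prediction as translation. The source sequence
concatenates the substrate SMILES (tokenized into *atomic tokens*: single
characters, except `Cl`/`Br`, bracketed atoms and `%NN` ring labels) with
the enzyme sentence (lowercased, byte-pair encoded, truncated to the top-k
most frequent subword tokens); both segments share one vocabulary with
reserved specials (`<pad> <s> </s> <unk> <sep>`). An encoder–decoder
transformer is trained under one of three regimes:

* **single** — one corpus only;
* **STL** — sequential transfer learning: pretrain on a large
  general-chemistry corpus, fine-tune on the enzymatic corpus;
* **MTL** — multi-task transfer learning: jointly train on a weighted
  mixture (reference weights 1 enzymatic : 9 general).

Optimization is Adam under the noam schedule
`lr = base_lr · d^(-1/2) · min(s^(-1/2), s · w^(-3/2))`; decoding is n-best
beam search whose hypothesis confidence is the product of token
probabilities. Evaluation reports top-1/top-2 exact-match accuracy on
canonical SMILES (stereo-exact and stereo-agnostic), invalid-SMILES rates,
stratifications by "-ase"-word count, enzyme-combination training
frequency, lipase-only and enantioselective subsets, and equal-frequency
confidence calibration with the 0.98/0.80 decision thresholds.

Everything is exercisable offline through a bundled synthetic generator
that emulates the structure of a literature-derived enzymatic corpus
(enzyme-determined transformations and stereochemistry, lipase-heavy
family skew, organism/strain/mutation tokens) plus a general-chemistry
companion corpus. The transformer itself is implemented in this package
(pre-norm architecture, hand-written backpropagation; a single-precision
RcppArmadillo core with the pure-R reference path kept as its numerical
oracle). SMILES handling (canonicalization, validity, randomized
renderings) goes through Open Babel via ChemmineOB.

## Worked example

```r
library(enzrxn)

## a desk-scale benchmark: 5000 enzymatic + 25000 general reactions
prep <- prepare_benchmark(generator_config(seed = 101))
prep$pair
#> <tokenizer_pair> vocab: 326 ( 21 SMILES, 300 text, 5 special )

## train the full-sentence multi-task model (2 layers, dim 128)
fit <- train_cell(prep, "full_sentence", "mtl",
                  model_config(dropout = 0),
                  training_schedule(valid_every = 1000))

## predict products for held-out reactions (unseen products by construction)
rep <- evaluate_cell(fit$model, prep$pair, prep$enz_test[1:250, ],
                     "full_sentence")
rep
#> <evaluation_report> n=250  top1 30.8%  top2 52.0%  invalid1 0.4%  invalid2 0.6%
```

`top1` is the fraction of test reactions whose canonical product —
stereochemistry included — is the model's first proposal; `invalid1` is the
fraction of first proposals that are not parseable SMILES. The jump from
top-1 to top-2 reflects the beam's second hypothesis frequently being the
other stereoisomer. A text-blind model trained identically
(`mode = "no_text"`) is far weaker (top-1 17.6% in this run, and only 9.6%
on the stereo-informative half of the benchmark, where the sentence is the
*only* signal deciding both the transformation type and the (R)/(S)
outcome). Evaluating the full-sentence model with sentences scrambled
between reactions collapses its accuracy to 9.2% — the model uses the
actual enzyme information, not the mere presence of text.

Single reactions work too:

```r
ck <- load_model("model.rds")   # checkpoints carry the tokenizer
src <- encode_source(ck$pair, "CCC(=O)c1ccccc1",
                     "alcohol dehydrogenase from lactobacillus kefir",
                     mode = "full_sentence", strict = FALSE)
decode_to_smiles(ck$model, ck$pair, list(src), beam_width = 5, n_best = 2)
```

A command-line entry point is installed as `exec/ert` with subcommands
`synth`, `tokenize`, `split`, `stats`, `train`, `predict`, `evaluate` and
`experiment`; run it without arguments for the synopsis.

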
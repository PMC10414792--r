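---
title: "Stacked convolutional ensembles for neuropeptide prediction: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stacked convolutional ensembles for neuropeptide prediction: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem and the model

`pepstack` classifies short peptides (5–100 residues over the 20 natural
amino acids) into a positive class (neuropeptides) and a negative class.
The model is a two-level stacked ensemble:

1. **Four sequence encoders** turn each peptide into a fixed-shape numeric
   matrix. Sequences are first right-padded with the out-of-alphabet
   character `B` to a common length (default 100), so residue positions
   stay anchored to the N-terminus.
   * *One-hot* (`encode_onehot()`): 100 × 20; each natural residue is a
     basis vector, each pad row is the constant 0.05 = 1/20, the uniform
     average residue frequency, so padding carries no positional
     preference.
   * *AAIndex* (`encode_aaindex()`): 100 × 14; row *i* holds 14
     physicochemical property values of residue *i* (hydrophilicity,
     solvation, contact energy, helix/sheet propensities, polarity,
     hydropathy, size/volume measures, flexibility). Pad rows take the
     per-property mean over the 20 residues.
   * *g-gap dipeptide* (`encode_ggap()`): 440 × 10; the 21 × 21 ordered
     residue pairs minus the pure-pad pair `BB` give 441 − 1 = 440
     composition bins. A pair `(s[i], s[i+g+1])` (default g = 0, adjacent
     dipeptides) seen *c* times sets column *c* of its bin's row, clipped
     at 10. This is a set-of-counts representation: all positional
     information is deliberately discarded.
   * *word2vec* (`encode_word2vec()`): 100 × d (default d = 32); row *i*
     is the skip-gram embedding of residue *i*, trained on the training
     sequences only (`train_word2vec()`).
2. **One compact 1-D CNN per encoder** (`train_cnn()`): convolution along
   the first axis with the second axis as channels, ReLU, max pooling,
   flatten, dropout, a dense ReLU layer and a sigmoid output, trained with
   Adam on binary cross-entropy.
3. **Stacking** (`pepstack_fit()`): records are assigned to *k* stratified
   folds (default 5); each CNN is trained on every fold complement and
   scored on the held-out fold, yielding one *out-of-fold* probability per
   encoder and sample. The 4-column matrix of those probabilities — in the
   fixed order `p_onehot`, `p_aaindex`, `p_ggap`, `p_word2vec` — trains
   the meta-learner, by default a Gaussian naive Bayes classifier
   (`gnb_fit()`) implemented in the package. Because every meta-feature
   comes from a model that never saw the sample, the meta-learner trains
   on honest probabilities. Alternatives via `fit_meta()`: logistic
   regression, AdaBoost (decision stumps, SAMME), gradient-boosted trees
   and XGBoost.

Reported cross-validated performance is also leakage-free: the
meta-learner is refit per fold on the other folds' out-of-fold rows, and
the word2vec table is retrained per fold on that fold's training part.

## Interpretation

With only four meta-features, Shapley values of the meta-learner's
posterior are computed exactly (`exact_shapley()`, `explain_model()`): all
2^4 = 16 coalitions are enumerated and the coalition value is the
interventional expectation over a background sample. No approximation is
involved, so efficiency (attributions sum to prediction minus baseline),
dummy and symmetry hold to floating-point accuracy.

## Key parameters and their defaults

| Parameter | Default | Rationale |
|---|---|---|
| `target_len` | 100 | upper end of the accepted peptide length range |
| CNN `filters` / `kernel` / `dense_units` | 32 / 5 / 64 | compact; a kernel of 5 spans a short linear motif |
| `dropout` | 0.5 | strong regularisation for small peptide sets |
| `epochs`, `batch_size`, `learning_rate` | 50, 64, 1e-3 | conservative Adam settings; `grid_search()` tunes by cross-validated AUC |
| `pool_size` | `NULL` (global); 4 for the g-gap CNN | see below |
| word2vec `d` / `window` / `epochs` | 32 / 5 / 100 | small vocabulary (21 tokens) needs few dimensions |
| `g` | 0 | adjacent dipeptides |
| `count_cap` | 10 | largest pair count observed in typical 5–100 residue sets |
| `k` | 5 | standard stratified CV |
| `var_smoothing` | 1e-9 × max pooled feature variance | keeps near-constant meta-features from collapsing the Gaussian likelihood |
| decision threshold | 0.5 | posterior ≥ 0.5 is labelled positive |

## Numerical choices worth knowing about

* **Encoder-specific pooling.** Global max pooling is position-blind: it
  reports *whether* any filter fires, not *where*. For the positional
  encoders that is exactly right (a motif can sit anywhere), but the g-gap
  encoder's signal is *which of the 440 bins are set* — its first axis is
  an index, not a position — and global pooling erases that entirely,
  leaving the classifier at chance. The g-gap CNN therefore uses local
  max pooling with window 4 (stride = width), preserving coarse bin
  identity; the other three pool globally.
* **AAIndex standardisation.** The raw 14 property scales span three
  orders of magnitude (solvation free energies near ±0.8, volumes above
  100). `encode_aaindex(scale = TRUE)` (the default) standardises each
  property to zero mean and unit variance over the 20 residues so no
  single property dominates the convolution input. Set `scale = FALSE`
  for raw values.
* **Word2vec without sampling.** The vocabulary has 21 tokens, so the
  full-softmax skip-gram loss and its exact gradient depend only on the
  center/context co-occurrence counts. Training is deterministic
  full-batch Adam on those counts — no negative sampling, no stochastic
  sweeps — and reproducible bit for bit from its seed.
* **Determinism.** All randomness (weight initialisation, minibatch
  shuffling, dropout, fold assignment, simulation) flows from explicit
  integer seeds through an RNG-state-restoring helper, so library calls
  never disturb the caller's random number stream. Max-pooling ties break
  toward the first position.
* **Metric edge cases.** `compute_metrics()` returns MCC = 0 with a
  warning when a factor of its denominator is zero, and `NA` sensitivity
  (specificity) with a warning when the positive (negative) class is
  empty. `confusion()` labels a score exactly at the threshold as
  positive. `auc_score()` is the rank-based Mann–Whitney statistic with
  ties counted one half, which equals the all-pairs definition exactly.
* **Gaussian naive Bayes from first principles.** Per class and feature,
  the sample mean and the population-divisor (1/n) variance plus the
  smoothing floor; posteriors are evaluated in log space with a max-shift,
  so extreme inputs give 0/1 rather than `NaN`.

## The synthetic benchmark and what it can show

No curated peptide data ship with the package. `simulate_peptides()`
generates balanced sets of variable-length peptides (5–100) from a
background residue model (uniform by default; `swissprot_freqs()` for a
protein-like composition), and overwrites a fixed motif (default the
5-mer `WKRFC`) onto each positive at a uniform position with probability
`motif_rate`. Overwriting, not inserting, keeps the length distribution
identical between classes.

The package's own study-scale checks use 400 peptides (200 per class),
25-epoch base classifiers and 32-dimensional embeddings — sizes chosen to
run comfortably on one CPU core in a few minutes while giving every
encoder enough signal to be individually informative. On this benchmark
all four base classifiers reach high out-of-fold AUC, stacking preserves
the best of them, 5- and 10-fold estimates agree closely, and permuting
the labels collapses cross-validated AUC to chance.

These checks validate the *machinery* — encoders, training, stacking,
evaluation and attribution — not biological performance. A planted
deterministic motif is far easier than real neuropeptide signal;
performance numbers on the synthetic benchmark say nothing about
performance on curated data, which users must evaluate themselves via
`read_fasta()` + `pepstack_fit()`.

## Limitations

* The CNNs are plain R + BLAS; they are fast at these problem sizes but
  not a substitute for a deep-learning framework at scale.
* Only the 20 natural residues are accepted; sequences with ambiguity
  codes (`B`, `J`, `O`, `U`, `X`, `Z`) are rejected rather than imputed.
* The CBOW option of `train_word2vec()` trains the reversed objective and
  is provided for experimentation only.
* The Gaussian naive Bayes meta-learner assumes conditionally independent
  meta-features; when base classifiers are highly correlated its
  posteriors can be overconfident, though ranking (AUC) is typically
  unaffected. The `fit_meta()` alternatives are there for exactly this
  comparison.

## A worked example

```{r example}
library(pepstack)

recs <- simulate_peptides(n_pos = 200, n_neg = 200, seed = 1)
fit <- pepstack_fit(recs, base_configs = default_base_configs(epochs = 25),
                    k = 5, seed = 1)
glance(fit)           # one-row summary: stacked + per-encoder AUCs
tidy(fit)             # per-fold CV metrics
autoplot(fit$cv)      # fold-level metric spread

new_peps <- simulate_peptides(n_pos = 20, n_neg = 20, seed = 2)
predict(fit, new_peps)

shap <- summarize_shap(explain_model(fit))
autoplot(shap)        # which encoder drives the ensemble
```
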
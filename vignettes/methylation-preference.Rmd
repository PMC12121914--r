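---
title: "Predicting transcription factors and their methylation preference from sequence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting transcription factors and their methylation preference from sequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylTF)
```

## The problem

DNA methylation at CpG dinucleotides was long viewed as a signal that
blocks transcription-factor (TF) binding, but a sizable subset of TFs —
"methylation readers", here called TFPMs — preferentially bind
*methylated* DNA. Identifying them experimentally (mass spectrometry,
HT-SELEX) is expensive, so a sequence-based screen that ranks candidate
methylation readers is a useful first filter before wet-lab validation.

`methylTF` implements a two-step pipeline:

1. **TF screening** — is a protein a transcription factor at all?
   Sequences are tokenized (CLS/SEP/PAD layout, fixed token budget),
   summarized by a CLS embedding, and classified by a linear + sigmoid
   head trained with binary cross-entropy.
2. **Methylation-preference classification** — given a TF, does it
   prefer methylated DNA? Sequences are rewritten in an 11-group
   reduced amino-acid alphabet, encoded as K-mer relative-frequency
   vectors, and classified by a radial-kernel SVM.

## The reduced-alphabet K-mer SVM

### Reduction schemes

A reduction scheme is a partition of the 20 canonical residues into
`op` groups, each written with one symbol. The canonical 11-group
partition is built in (`load_scheme("Op11")`); note its two symbol
quirks — cysteine carries the symbol `V` and the group {I, V} carries
`I` — which the package reproduces exactly:

```{r}
load_scheme("Op11")
```

The companion sizes used in grid search (`Op5`, `Op8`, `Op9`, `Op13`)
are shipped as plain-text scheme files. Only the 11-group table is
available verbatim from the clustering literature chain we follow; the
other four sizes are **reconstructed** as nested coarsenings or
refinements of the 11-group partition along physicochemical similarity
(e.g. `Op9` merges {I,V}+{L,M} and {H,S}+{T}; `Op13` splits the
aromatics and the charged/amide group). The files say so in their
headers. All headline behavior of the package uses `Op11` only, so this
reconstruction affects nothing but the breadth of the grid. `Op20` (the
identity scheme) is also built in; at K = 1 it reduces the encoding to
classical amino-acid composition, which is a useful limit for testing.
Schemes are validated as exact partitions at load time.

### K-mer features

A window of length K slides across the reduced sequence one residue at
a time, giving L − K + 1 overlapping windows; the feature vector counts
each of the `op^K` possible K-mers and divides by the window count.

Two deliberate choices:

* **Relative frequencies, not raw counts.** Protein lengths here span
  roughly 50–5,000 residues; raw counts at that spread would dominate
  the RBF distance `exp(-gamma * ||x - x'||^2)` and saturate the kernel
  at `gamma = 1`. Frequencies keep every feature in [0, 1] and sum to
  one, which is also why no further feature scaling is applied before
  the SVM.
* **Fixed lexicographic K-mer order** over the scheme's *declared*
  symbol order (first position most significant), so feature matrices
  are reproducible bit-for-bit across runs and machines.

Degenerate inputs: a sequence shorter than K is an error in strict mode
and an all-zero row (with a warning) in lenient batch mode, so one
short protein cannot abort a proteome-wide screen.

### The classifier

`tfpm_train()` fits a C-classification SVM with radial kernel on the
feature matrix, with no class weighting (the curated training data this
mirrors are imbalanced roughly 270:106, and the observed
sensitivity ≫ specificity pattern is consistent with unweighted
training) and `scale = FALSE` for the reason above. The operating
point, fixed by grid search in the source study, is the package
default: `op = 11`, `K = 1`, `C = 0.01`, `gamma = 1`, where `gamma` is
the literal kernel coefficient, never a data-dependent heuristic.

**Probability calibration.** Ranking and thresholding use a
Platt-style sigmoid `P(y = 1 | f) = 1 / (1 + exp(A f + B))` fitted on
the training decision values with smoothed targets, optimized by BFGS —
fully deterministic. ROC/AUC is always computed from the raw decision
values `f`, which are rank-equivalent to the calibrated probabilities;
this separation keeps AUC independent of the calibration step. We do
not use the SVM library's built-in probability machinery because its
internal cross-validation is randomized outside our seed control.

**Evaluation.** Sensitivity, specificity, accuracy and MCC come from
the confusion matrix (label 1 = TFPM; a probability of exactly 0.5 is
called positive — the inclusive rule); AUC is the exact rank
(Mann–Whitney) statistic with ties counting 1/2. Any metric with a
zero denominator is reported as 0 and flagged rather than raised, so
reports stay total. MCC with a zero denominator is likewise defined as
0 — a standard convention the evaluated datasets never exercise.

**Cross-validation and grid search.** Folds are stratified by class
and derived deterministically from a seed; held-out predictions are
pooled across folds for the overall report. The grid search is
exhaustive over (op, K, C, gamma), persists its full table, and
maximizes cross-validated AUC; exact AUC ties are broken toward the
earlier setting in lexicographic (op, K, C, gamma) order and logged.
Default grids, where not overridden: the five scheme sizes, K in 1..5,
`C` in `10^(-3..2)` and `gamma` in `10^(-2..1)` (the study text fixes
only the optimum, not the full grid, so the logarithmic grids are the
package's own choice and are overridable).

**Ranking.** `rank_proteome()` orders by calibrated probability
descending with ties broken by id ascending, returns the top n and
attaches the full table.

## The TF screening stage

The tokenizer standardizes every sequence to exactly `max_len` tokens
(default 1000): `[CLS, r1 … rm, SEP, PAD…]` with
`m = min(L, max_len − 2)`. Two conventions the tokenizer fixes where
the description we follow is silent:

* the token budget *includes* CLS and SEP (standard BERT accounting),
  so a 1000-token sequence carries 998 residues;
* truncation keeps the **N-terminal** prefix, the conventional choice.

Residues outside the canonical 20 tokenize as `X`. The head is
`sigmoid(w·e + b)` on the CLS embedding with the inclusive 0.5 rule,
trained by full-batch gradient descent on the binary cross-entropy
`L = −(1/N) Σ [y log ŷ + (1−y) log(1−ŷ)]` (probabilities clipped to
`[1e−12, 1−1e−12]`), from a zero initialization — deterministic
bit-for-bit.

The embedding backend is pluggable. The package ships a **stub
backend**: a fixed random projection (drawn once from a seed) of the
token composition plus a coarse length term, passed through `tanh`. It
is deterministic, runs in milliseconds per thousand records, and
exercises the tokenizer/head/loss plumbing end to end. It is *not* a
protein language model: it sees composition, not context. Fine-tuning
a real transformer backend (the source study's configuration: 5
epochs, learning rate 5e−5, weight decay 0.1, no warmup, 1024-dim CLS
embeddings) requires GPU-scale external weights and is exposed only as
the `embedding_backend` contract plus this documented template; the
package's tested claims about the screening stage are therefore claims
about the plumbing, not about transformer accuracy.

## The synthetic-data generator

`synthetic_spec()` / `generate_dataset()` produce labeled two-class
protein sets with a *planted* composition difference: positives carry
`delta` extra probability mass on the residues of one reduced-alphabet
group (spread proportionally within the group, all other residues
down-weighted proportionally), negatives follow an approximate
vertebrate background composition. Residues are emitted i.i.d.;
lengths are log-normal (median 400, sigma 0.7 on the log scale) with a
floor of 50 and a cap of 5,000, which puts roughly 90% of sequences
under 1,000 residues — mimicking the real curated sets' "at least 50
residues" rule and their length distribution, under which a
1000-token budget covers ~90% of sequences.

What this emulates well: class sizes in the hundreds, realistic length
spread, and a composition-level signal — exactly the regime in which
the K = 1 classifier operates. What it deliberately does **not**
emulate: positional structure (motifs, domains), homology between
sequences, or any actual methylation-binding biology. Consequently,
passing tests show that the pipeline recovers composition signals at
realistic scales and stays at chance under the null; they do not show
that real TFPMs are separable — that claim rests on the curated
datasets, which ship with the original study, not with this package.
An i.i.d. emitter also means K ≥ 2 adds no information on synthetic
data (a Markov-chain emitter is the documented extension point if
K ≥ 2 sensitivity is ever to be tested positively).

With `delta = 0` both classes share one emission distribution exactly,
giving a clean permutation-style null: held-out AUC averaged over 20
replicate seeds sits near 0.5. With `delta = 0.15` on the
charged/amide group the held-out AUC exceeds 0.9 by a wide margin.

## Problem sizes and determinism

The test-suite and acceptance-script runs use training sets of 120–400
sequences, held-out sets of 80–200, 3–5 folds, and grids of a few dozen
settings — sizes at which every stage runs in seconds on one CPU while
the Monte-Carlo checks (20 replicate seeds for the null) retain enough
resolution for the stated bands. All randomness — sequence generation,
fold assignment — flows from explicit integer seeds; SVM fitting,
Platt calibration, head training and the stub backend are deterministic
given their inputs, so identical (data, hyperparameters, seed) yield
bit-identical models and predictions.

## Known limitations

* The curated human/mouse TFPM datasets and the fine-tuned transformer
  weights are external artifacts; the package validates its pipeline on
  synthetic data and exposes manifest/backend interfaces for the real
  ones.
* The four non-canonical scheme sizes are reconstructions (above);
  grid-search results across `op` should be read accordingly.
* Platt calibration on training decision values is optimistic on
  separable training sets (probabilities saturate); ranking is
  unaffected since calibration is monotone.
* Redundancy filtering (e.g. clustering at a similarity threshold) is
  upstream curation, out of scope here; `load_dataset()` assumes its
  inputs are already non-redundant.

## A complete run

```{r, message = FALSE}
train <- generate_dataset(synthetic_spec(n_pos = 120, n_neg = 120,
                                         effect_group = "E", delta = 0.15,
                                         seed = 1))
test  <- generate_dataset(synthetic_spec(n_pos = 60, n_neg = 60,
                                         effect_group = "E", delta = 0.15,
                                         seed = 2))
model <- tfpm_train(train, tfpm_hyperparams(op = 11, k = 1,
                                            C = 0.01, gamma = 1))
pred <- predict(model, test$records)
compute_metrics(confusion(test$labels, pred$label),
                auc = roc_auc(test$labels, pred$score))
rank_proteome(model, test$records, top_n = 5)[, c("id", "probability")]
```
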
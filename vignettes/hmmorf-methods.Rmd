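---
title: "Predicting MoRFs from HMM profiles: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting MoRFs from HMM profiles: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmmorf)
```

## The problem

Molecular Recognition Features (MoRFs) are short stretches — typically 5
to 25 residues — inside intrinsically disordered protein regions that
fold upon binding a partner protein. Because the surrounding sequence is
disordered, MoRFs carry little structural signature of their own; what
distinguishes them best is their evolutionary conservation profile.
`hmmorf` scores every residue of a query sequence with a propensity in
[0, 1] of belonging to a MoRF, using only the per-position amino-acid
emission probabilities of an HMM profile computed externally by HHblits
(HH-suite). The package deliberately emits *only* a propensity track, no
binary calls: sensible cutoffs differ between proteins, so thresholding
is left to the evaluation utilities.

## From profile to features

An HH-suite `.hhm` file stores, for each of the `L` match states, 20
match-emission scores plus 10 insert/transition columns. Scores `N` are
integer-quantised negative log-probabilities; `score_to_probability()`
inverts them with

\[ p = 2^{-N/1000}, \]

so `N = 0` is probability 1 and the `*` sentinel ("infinite score") maps
to probability 0, the transform's limit. Only the 20 match-emission
columns are used; the insert/transition columns are parsed and
discarded. The parser reorders columns to the fixed order
`A C D E F G H I K L M N P Q R S T V W Y` whatever order the file
declares, so downstream feature vectors never depend on column layout.

The feature vector for residue `c` at window flank `f` is the
row-major concatenation of profile rows `c - f … c + f` — a vector of
length `(2f + 1) × 20`. Rows falling outside the sequence are all-zero,
at training *and* test time: the SVMs need a fixed dimension, and a zero
emission row is the natural encoding of "no residue". The window size
`w = 2f + 1` is always odd and centred on the query residue; the
published model table indexes some models by window and some by flank,
which are consistent only under this relation, so the package adopts it
throughout.

## Regions, segments and sampling

Each annotated training sequence is partitioned into three regions:
**MoRF** (annotated interval residues), **Flank** (the 12 residues on
each side of a MoRF, truncated at the termini) and **Other** (the rest).
When two MoRFs sit closer than two flank widths apart, the residues
between them remain Flank — never Other — so negatives are always well
clear of an annotated MoRF. Flank width is configurable
(`annotate_regions(flank_len=)`) but the ensemble never changes the
default of 12.

Training windows are drawn from two segments: segment A, the MoRF
residues, provides one positive per MoRF residue (its window reaches
into the flanks, which is intended — the flank context is part of what
distinguishes a MoRF); segment B, the Other residues, is the negative
pool. Negatives are drawn uniformly *without replacement* from the pool
of Other positions of all sequences together, `ratio` per positive
(ratio 1, 2 or 3; the default ensemble uses 1 or 2 per model). Pooling
across sequences, rather than matching counts per sequence, keeps the
ratio exact even when individual sequences have few Other residues; a
pool smaller than the request is a hard error rather than silent
sampling with replacement. Each ensemble member re-draws its own
negatives with its own seed (`master_seed + model index`), so the nine
models see different negative sets.

## The nine-model SVM ensemble

The ensemble is fixed by `default_ensemble_spec()`:

| model | window | kernel  | gamma  | ratio |
|------:|-------:|---------|-------:|------:|
| 1     | 11     | RBF     | 0.0038 | 1:2   |
| 2     | 7      | RBF     | 5      | 1:2   |
| 3     | 3      | sigmoid | 5      | 1:2   |
| 4     | 13     | RBF     | 0.0038 | 1:2   |
| 5     | 9      | RBF     | 5      | 1:1   |
| 6     | 5      | sigmoid | 5      | 1:2   |
| 7     | 7      | RBF     | 0.0038 | 1:2   |
| 8     | 13     | RBF     | 5      | 1:2   |
| 9     | 7      | sigmoid | 5      | 1:1   |

All models use C = 1000. The mix of kernels is deliberate: RBF models
tend to over-score data resembling their training set while sigmoid
models are more conservative, and averaging across both (plus across
window sizes and negative draws) damps the bias of any single model.
Fitting goes through libsvm (the `e1071` binding) with `scale = FALSE`:
features are already probabilities on a common [0, 1] scale, and
rescaling would silently change the meaning of the published gamma
values.

Per-residue model outputs are Platt-scaled class probabilities rather
than raw decision values. Decision values of an RBF and a sigmoid
machine live on incompatible scales, so averaging them directly would
weight models arbitrarily; calibrated probabilities are commensurable by
construction. The fused propensity is the plain arithmetic mean of the
nine per-model scores ("common averaging"); it is therefore always
bounded by the per-model extremes.

Determinism: every source of randomness — negative draws and the
internal cross-validation of the Platt calibration — is seeded from the
single master seed, fanned out per model, so a training run is exactly
reproducible.

## Evaluation metrics

Three metrics, all on per-residue scores with *every* non-MoRF residue
(flanks included) counted as a negative:

* **AUC** — trapezoidal area under the empirical ROC with tied scores
  grouped into single vertices; algebraically equal to the Mann-Whitney
  pairwise statistic with ties counted one half.
* **FPR / accuracy at fixed TPR** — the benchmark operating points are
  TPR = 0.222 and 0.389. The threshold is the most conservative ROC
  vertex whose TPR reaches the level, with no interpolation between
  vertices: every reported number is then exactly reproducible from the
  finite score set.
* **Success rate** — the fraction of sequences whose mean propensity
  over true MoRF residues *strictly* exceeds the mean over non-MoRF
  residues. Ties count as failure (the comparative wording of the
  metric demands an actual excess), and sequences lacking one of the two
  classes are excluded from the denominator with a logged count. The
  literature delegates the exact formula to earlier benchmark papers;
  this per-sequence mean comparison is the package's documented reading.

## The synthetic benchmark

Real MoRF benchmarks need an HHblits run against a large sequence
database, which is outside this package's scope. `generate_dataset()`
instead fabricates a complete benchmark — FASTA, annotation TSV and
`.hhm` files — with a *planted* signal:

* each sequence draws a background composition from a symmetric Gamma
  prior (`concentration`, default 5: realistic per-protein composition
  variability without degenerate near-zero frequencies);
* each planted MoRF (default one per sequence, length uniform in 5-25,
  uniform placement) gets a composition interpolated with weight
  `signal` toward a fixed hydrophobic/aromatic-enriched target
  (I, L, V, F, W, Y, M) — the residue classes real MoRFs bury in their
  binding interface;
* flank rows ramp linearly from MoRF to background composition over 12
  residues, mimicking gradual conservation decay;
* per-residue rows add log-normal noise (`noise_sd`, default 0.25) and
  are renormalised, quantised to the integer `.hhm` score grid
  (probabilities below `2^(-32.767)` become `*`), and residue letters
  are drawn from each row's composition.

At `signal = 0` MoRF and background rows come from *exactly* the same
distribution, so any detector should fall to chance; at `signal = 1`
MoRF rows follow the fixed contrasting profile. Defaults: 10 sequences
of 60-120 residues — experiment-scale runs use 60 training and 40 test
sequences at `signal = 0.9`, the package's standing study condition for
the recovery experiment, and 30/20 sequences per replicate for the
null-signal calibration (five replicates).

What the generator does *not* emulate: genuine evolutionary
correlations between neighbouring positions, insert-state statistics,
disorder context, or the length-dependent composition biases of real
IDRs. Passing the recovery experiment therefore shows the pipeline
plumbing, seeding, windowing and fusion are sound and that the ensemble
can learn a compositional contrast — it does not certify accuracy on
real proteins, which depends on real HHblits profiles.

A note on the null calibration: held-out AUC at `signal = 0` sits
slightly above 0.5 (≈0.54 over five replicates) rather than exactly at
chance. The residual is positional, not compositional: planted MoRFs
are never closer to a terminus than their own length allows, while
Other residues include the termini, whose windows are partially
zero-padded — so "distance from terminus" leaks weakly into the labels.
The effect is inherent to terminus padding in windowed per-residue
classification, and small.

## Numerical choices and degenerate inputs

* `.hhm` quantisation rounds to the nearest integer score; the
  round-trip error is bounded by a factor `2^(1/2000) - 1` ≈ 0.035% of
  the probability.
* `*` entries always mean probability 0, both directions.
* Windows at termini are zero-padded rather than clipped or reflected.
* A training set whose segment B cannot supply the requested negatives
  aborts with advice to lower the ratio.
* Sequences present in a FASTA but lacking a profile are skipped with a
  warning; annotations for unknown sequences likewise.
* Annotation intervals are 1-based inclusive on disk; interval lengths
  outside 5-25 are accepted with a warning (the generator never emits
  them, but external annotations may).

## Known limitations

* Platt scaling requires an internal cross-validation, so per-model
  probabilities are only as stable as that calibration on small
  training sets; with fewer than a few dozen positives the fused track
  gets noticeably noisy.
* The ensemble hyperparameters are fixed constants taken over from the
  published grid search on the real benchmark; they are not re-tuned
  for the synthetic data, and no automated grid search ships with the
  package.
* Scoring is single-threaded; throughput is dominated by the two
  widest-window RBF models.
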
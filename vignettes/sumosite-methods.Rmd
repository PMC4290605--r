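---
title: "Predicting sumoylation sites from sequence windows: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting sumoylation sites from sequence windows: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sumosite)
```

## The problem

Sumoylation is the reversible attachment of a SUMO protein to a lysine
residue of a target protein, mediated by the E1/E2(UBC9)/E3 enzyme
cascade. Roughly three quarters of experimentally known sites conform to
the consensus motif ΨKxE/D — a large aliphatic hydrophobic residue (Ψ),
the modified lysine, any residue, then glutamate or aspartate — which
makes plain motif matching a strong but imperfect baseline: about a
quarter of true sites are non-consensus, and many consensus contexts are
never modified. `sumosite` predicts sumoylation sites from the local
sequence context of each candidate lysine, with the consensus scanner
(`[IVLMAP]K.[DE]`) kept as the reference baseline.

## Windows and features

Each candidate lysine is represented by a 7-residue window: three
upstream slots `w-_1..w-_3` and three downstream slots `w+_1..w+_3`,
numbered so that `w-_3` and `w+_1` are adjacent to the lysine (an alanine
immediately before the lysine is the feature `w-A_3`). Lysines closer
than three residues to a terminus are kept, with the out-of-range slots
marked padded. The encoder builds 137 features per site:

* **120 positional one-hot indicators** — each of the 20 standard amino
  acids at each of the 6 flanking slots.
* **6 hydrophobicity values** — the Hopp–Woods hydrophilicity of each
  flanking residue (`w-1_Hydro` … `w+3_Hydro`).
* **Consensus** — the motif predicate above, as a binary feature.
* **wDE / wK** — position-unspecific presence of an acidic residue /
  an extra lysine anywhere in the flanks.
* **Flexible, DisorderReal, DisorderBinary** — conformational
  flexibility (0/1) and intrinsic-disorder tendency (real in [0, 1], plus
  its 0.5-cutoff binarization) of the central lysine, consumed from an
  external per-residue annotation file. The original predictors
  (FlexPred, IUPred) are external tools; `null_annotations()` supplies
  all-zero annotations so the pipeline runs without them, which is also
  the "without flexibility & disorder" ablation.
* **TerminalBinary, SignedLength** — whether the site lies within 10% of
  either terminus, and the protein length negated for terminal sites.
* **BeforeVol, AfterVol, Difference** — Kharakoz residue volumes summed
  over each 3-residue sub-window, and downstream minus upstream.

That is 126 binary and 11 real-valued features; the decomposition is
asserted at package load. Both lookup tables are transcribed from their
primary sources (Hopp & Woods 1981; Kharakoz 1997) and shipped as code
constants, since neither is tuned by the package.

Numerical conventions, chosen where the convention was genuinely open:

* Padded and non-standard residues (X, B, Z, U) contribute 0 to one-hot,
  hydrophobicity and volume features — 0 is the neutral value under
  min–max scaling and keeps the dimensionality fixed near termini.
* `DisorderBinary` uses an inclusive cutoff (tendency ≥ 0.5 maps to 1).
* The terminal test is an exact fractional comparison
  (`pos <= 0.1 L` or `pos > 0.9 L`), with no integer rounding of `0.1 L`.
* Scaling is min–max to [0, 1], fitted on the training matrix only;
  constant columns map to 0; test values outside the training range are
  **not** clamped, so they may fall outside [0, 1]. All 137 features pass
  through the same scaler (binary columns that contain both values are
  unchanged by it).

## ReliefF feature ranking

Features are ranked by ReliefF merit: for every instance, the k nearest
same-class neighbours (hits) and k nearest other-class neighbours
(misses) are found under Manhattan distance on range-normalized
features, and each feature accumulates the weighted feature mismatch
with misses minus the mismatch with hits, averaged over all instances.
Neighbours are weighted by their distance rank, `exp(-(rank/σ)²)`
normalized to sum to one. Defaults are k = 10, σ = 2, all instances
sampled — the classic implementation's defaults with distance weighting
switched on. Ties in merit break by canonical feature order; neighbour
ties in distance break by instance index, making the ranking
deterministic and invariant to instance order.

The number of features to keep is then chosen by a wrapper loop: the
classifier is evaluated on the top-c features for increasing c by
stratified 10-fold cross-validation, and the count with the highest MCC
wins (ties toward fewer features). The SVM hyperparameters are held
fixed across counts rather than re-tuned per count; this keeps the loop
tractable but can in principle under-rate feature subsets that would
prefer different hyperparameters. A `stride` parameter coarsens the
curve when 137 nested models are too expensive.

## The classifier

The model is a C-classification SVM with an RBF kernel (libsvm, via
e1071), trained on the scaled selected features. Class imbalance
(~4% positives) is handled by class weights rather than resampling: the
per-class effective penalty is `weight × C`, with weights 1:5
(negative:positive) by default. The stated "1:5" is read as up-weighting
the positive minority class, consistent with its motivation of
countering imbalance; the orientation is configurable.

Hyperparameters come from an exponential grid search: C over
2⁻⁵…2¹⁵ and γ over 2⁻¹⁵…2³, doubling each step (21 × 19 = 399 points).
The search objective is stratified cross-validated MCC (the original
description names MCC for model selection elsewhere but not the grid
criterion; MCC is used here throughout), with the same fold assignment
reused across grid points so comparisons are paired. If the optimum
lands on a grid border, the grid extends stepwise up to 5 exponent steps
beyond the original margins.

Predictions act on raw decision values, oriented so larger means more
confidently positive; no probability calibration is used. Named
thresholds low/medium/high = −0.5/0/0.5 trade sensitivity against
specificity, and any numeric threshold (e.g. −0.4) can be given
directly. Sensitivity is non-increasing and specificity non-decreasing
in the threshold, which the tests assert over a dense sweep.

## Statistical screening

Three comparison strategies are run feature by feature: positive vs
negative windows, consensus vs non-consensus positives, and consensus vs
non-consensus negatives. Binary features use the Pearson chi-square test
of independence on the 2×2 presence table, with the Yates continuity
correction applied exactly when some **observed** cell is below 5 (the
rule as literally stated; an expected-count variant is available).
Real-valued features use the two-tailed Mann–Whitney U test with
midranks, reporting the probability of superiority `PS = U/(n₁n₂)`
(oriented so PS estimates P(positive value > negative value)) and the
normal approximation `z = (U − n₁n₂/2) / √(n₁n₂(n₁+n₂+1)/12)`; the plain
(not tie-corrected) variance is the default to match the printed
formula, with a tie-corrected variant behind a flag. Benjamini–Hochberg
adjustment is applied within each strategy's family of tests (137 per
strategy), since results are reported per strategy; features constant
across both groups are kept as explicit "untestable" rows outside the BH
family.

## Evaluation

Performance is summarized by accuracy, specificity, sensitivity and
Matthew's correlation coefficient, with MCC defined as 0 when its
denominator vanishes. Cross-validation uses stratified random folds —
the original protocol says only "randomly divided", but with ~4%
positives unstratified folds can lack positives entirely, so
stratification is the package's choice and a noted deviation risk when
comparing to published numbers. Each CV analysis is repeated (25 times
in the reference protocol), metrics averaged over folds then repeats,
with per-repeat standard deviations retained. A self-consistency test
(train and evaluate on the same data) measures fitting capacity, and the
consensus-regex baseline is evaluated alongside for the standard
report layout. ROC curves are threshold sweeps with ties grouped
(trapezoidal AUC equals the probability a positive outscores a negative,
ties counted half); across repeats, TPR is vertically averaged on a
101-point FPR grid and the AUC is computed from the averaged curve.

## The synthetic-data generator

The generator exists so every stage is testable without the original
curated dataset. It emulates the reported statistical structure:

* the four-class mix of the published training accounting —
  consensus-positive 3.23%, non-consensus-positive 1.09%,
  consensus-negative 3.39%, non-consensus-negative 92.29%;
* positional marginal effects: Glu at `w+_2` 0.81 in positives vs 0.07
  in negatives; extra Lys at `w+_2` 0.01 vs 0.09 and at `w-_3` 0.03 vs
  0.09; Arg depletions 0.01 vs 0.06 / 0.01 vs 0.07; His at `w+_2` 0 vs
  0.03; Pro at `w+_3` 0.19 vs 0.06;
* flexibility 0.57 vs 0.44 and disorder 0.59 vs 0.39 at the central
  lysine.

Design choices, fixed once: effects are planted independently per
position given the class (the simplest model consistent with the
reported marginals); consensus positives draw Ψ from a fixed weight
table and E vs D at `w+_2` so that the positive-class Glu marginal is
0.81 overall, with "predominantly glutamate" in consensus positives;
non-consensus windows are guaranteed to break the motif by forcing a
non-Ψ residue before the lysine whenever `w+_2` is acidic, with Glu
planted in 30% of non-consensus positives; consensus negatives carry E
or D equally, matching the described logos. Disorder tendencies are
drawn as 0.5 ± 0.5·Beta so that the exceedance of the 0.5 cutoff equals
the class probability exactly. Background residues are uniform over the
19 non-lysine standard amino acids, so every lysine in a generated
protein is a labeled site; protein lengths are uniform on 100–600 so the
terminal-region feature takes both values. Everything is reproducible
from a single seed.

What the generator does **not** emulate: realistic proteome amino-acid
composition, higher-order positional correlations, the unknown joint
distribution of features in non-consensus positives (its independence
model is a stand-in), paralog structure, or PTM cross-talk such as the
acetylation–sumoylation switch. Passing tests on this data therefore
show that the machinery recovers planted structure of the reported kind
and size — not that real-data performance figures are reproduced.

## Problem sizes and what is (not) reproduced

The published headline figures — 5-fold CV MCC 0.66 / Sn 73% / Sp 98% /
Acc 97%, AUC 0.91 from the averaged ROC, the 93-of-137 feature optimum
and the published merit scores — were measured on the curated
experimental dataset with external FlexPred/IUPred annotations and are
not reproducible from this package alone. `reproduction_guide()` points
to the installed guide describing the input formats for a real-data
attempt. The package's own checks run on the generator at its default
scale, about 2,600 windows with ~4% positives: ReliefF ranking on the
full matrix; a coarsened tuning grid (C exponents −3…9, γ exponents
−11…−1, step 2, 3-fold CV) followed by 5-fold CV with 5 repeats in the
acceptance analysis. The grid stride, fold counts and repeat counts are
deliberate scale-downs of the full protocol (full grid, 10-fold, 25
repeats), chosen as reasonable desk-scale settings; the full settings
remain the defaults of `grid_spec()`, `select_feature_count()` and
`cross_validate()`.

At this scale the pipeline reproduces the reported structure
qualitatively: `w+E_2`, `Consensus` and `wDE` emerge as the top-ranked
features in that order; the tuned weighted SVM exceeds the regex
baseline's MCC; and sensitivity/specificity trade off across the
low/medium/high thresholds as published. The quantitative values on
synthetic data (written by `scripts/acceptance.R`) land close to, but
are not expected to equal, the real-data figures.

## Known limitations

* Window geometry is fixed at 3+3; the encoder refuses other sizes.
* Mann–Whitney p-values are asymptotic (normal approximation), not
  exact; for tiny groups they are crude.
* The wrapper selection reuses one (C, γ) for every feature count.
* Whether the original work scaled binary features, used ≥ or > at the
  disorder cutoff, pooled BH across strategies, or stratified its folds
  is unknown; each choice here is documented above and, where
  reasonable, configurable.
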
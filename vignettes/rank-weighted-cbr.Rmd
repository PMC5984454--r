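---
title: "Rank-weighted case-based reasoning for plasma thermograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-weighted case-based reasoning for plasma thermograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rankcbr)
```

## The problem

Differential scanning calorimetry of blood plasma produces a *thermogram*:
the excess heat capacity (ΔCp) of the sample recorded on a fixed temperature
grid, here 451 points from 45 to 90 °C. The curve's shape reflects the
thermal denaturation of the plasma proteome and typically shows one or two
peaks — a lower-temperature peak in the 45–55 °C range and a dominant peak
above 55 °C. Shifts in peak location and in the balance of the two peaks
track clinical status, which makes thermograms attractive as a cheap
screening readout. They are also hard to classify: between-subject
variability within a class is large, and many profiles simply do not follow
their class's "typical" shape, so classifiers that compare a subject to a
class average do poorly.

Case-based reasoning (CBR) sidesteps the class average entirely: a target
case is labelled by retrieving the most similar *individual* stored case.
`rankcbr` implements a CBR classifier for thermogram cohorts whose two
distinctive ingredients are (i) a global similarity built from the
*rank order* of per-feature distances rather than their magnitudes, and
(ii) feature weights estimated from Wilcoxon rank-sum tests on a training
set (the RWCBR variant), alongside the standard comparators: equal weights
(CLCBR), entropy weights (ETCBR), logistic-Wald weights (LWCBR), a k-NN
baseline, and a composite-coefficient statistical baseline (SCUCC).

## Features and local distances

Each subject is reduced to six features. Five are scalars extracted from
the curve after Gaussian-kernel (Nadaraya–Watson) smoothing: the initial
response flag IR (1 if the smoothed curve rises over its first
`initial_window` = 2 °C, else 0), the peak locations T1 ∈ [45, 55] and
T2 ∈ (55, 90], and the peak heights PEAK1 and PEAK2 (the window maxima of
the smoothed curve). The sixth feature, IND, is the raw 451-point curve
itself. Window boundaries are chosen so every grid point belongs to exactly
one window; argmax plateaus resolve to the lowest temperature; a flat
initial segment counts as non-increasing. The default bandwidth is 1 °C —
narrow enough to keep two peaks separated by a few degrees distinct, wide
enough to keep a 0.3-unit noise floor from relocating an argmax. IND enters
distance computation unsmoothed: it is the default measurement, and the
Fréchet distance used on it is itself shape-driven rather than
noise-sensitive.

Local distances are per-feature: squared Euclidean for the scalars (the
square is deliberately kept — only ranks are consumed downstream, and ranks
are invariant to any strictly increasing transform) and the discrete
Fréchet distance for IND, computed by the standard dynamic program over the
coupling lattice with plain Euclidean ground metric in the
(temperature, ΔCp) plane. On sampled curves the discrete variant
upper-bounds the continuous Fréchet distance; at a 0.1 °C grid step the gap
is negligible compared with between-subject distances. Whether temperature
should be a ground-space coordinate at all is a genuine modelling choice;
including it penalises couplings that match far-apart temperatures, which
is what "same shape at a similar temperature" means clinically. No axis
rescaling is applied by default.

## Rank-order similarity

For a target case, each feature's distances to all n stored cases are
converted to *dense ranks*: tied distances share a rank and the largest
rank equals N′, the number of distinct distance values. The global
similarity of stored case i is

S(i) = Σ_f ω_f · (N′_f − rank_f(i)) / (N′_f − 1),

so the nearest case on a feature contributes 1 and the farthest 0. With
weights on the simplex, S ∈ [0, 1], and S = 1 exactly when the case is
rank-1 on every feature. Dense ranking is what makes this normalisation
exact: a "min"-style competition rank can exceed N′ and would drive terms
negative. A feature with a single distinct distance value (N′ = 1) is
uninformative for ordering; it contributes the constant 1, which preserves
the case ordering and keeps the upper bound attainable. Classification is
k-NN on S (k = 1 for all CBR variants, matching classical CBR retrieval);
a 50/50 vote at even k predicts control, the conservative call for a
screen, though with k = 1 it never triggers.

## Feature weighting schemes

**RWCBR (rank weights).** For weight estimation each training case is
reduced, per feature, to a scalar score: its local distance to a fixed
control-class reference case, built as the feature-wise median of the
control training cases (point-wise median curve for IND). A Wilcoxon
rank-sum test then compares cancer scores against control scores, and
weights are allocated as ω_f ∝ 1 − p_f, normalised to sum 1. The p-value is
two-sided; exact (via the null U distribution) for pooled samples of at
most 12 without ties, otherwise a normal approximation with tie-corrected
variance and continuity correction. The median reference is the package's
resolution of an ambiguity: the weight objective is written as a
distance-to-a-reference rank sum, but the published per-fold weights are
target-independent, so the reference must be a fixed training-set
construct. A mean-distance-to-all-cases variant is available
(`reference = "average"`), but note that in a balanced cohort a pure
location shift leaves mean distances symmetric between classes, so that
variant cannot single out a shifted feature — one reason the control-median
reference is the default.

**ETCBR (entropy weights).** Label-free: weight ∝ information content. IR
is treated as Bernoulli (Shannon entropy in bits), the scalars as normal
(differential entropy ½·log₂(2πeσ̂²), floored at 0 since differential
entropy is negative for σ below ≈ 0.24 on the log₂ scale and the
standardisation presumes nonnegative entropies), and IND as the *sum* of
per-grid-point floored normal entropies. The sum (rather than mean) makes
the 451-point curve dominate the weight vector, which is the behaviour this
scheme is known for on thermogram features. Differential entropy is
unit-dependent, so this is the one scheme sensitive to the ΔCp scale.

**LWCBR (Wald weights).** A binary logistic regression of the label on the
six predictors, with IND reduced to its trapezoidal area under the curve —
a 451-dimensional predictor is unfittable on a few dozen cases, and total
denaturation enthalpy is the natural one-number summary. Predictors are
standardised; the IRLS solver carries a ridge penalty of 1e-4 so separable
training sets still converge to a finite fit (at most 100 iterations;
non-convergence raises an error carrying the last iterate). Weights are
the squared Wald statistics (β̂/se)², intercept excluded, normalised; if
every statistic is numerically zero the scheme falls back to equal weights.

**CLCBR** gives each feature 1/6.

## Evaluation harness

`run_experiment()` performs stratified k-fold cross-validation (default 5
folds): each class is shuffled under the run seed and dealt round-robin, so
a balanced 70-subject cohort yields exactly 7 + 7 test cases per fold (14
test, 56 train). Weights are estimated on the training fold only; the
retain step of the CBR cycle is never invoked during evaluation, so test
cases cannot leak into the case-base. Per fold and model the harness
reports precision, recall, F-1 (harmonic mean) and G-measure (geometric
mean), with cancer as the positive class and zero denominators reported as
0 with a warning; summaries are MIN/AVG/STD/MAX with the sample (n − 1)
standard deviation. The k-NN baseline (k = 5) sums per-feature local
distances after min–max scaling each feature's distance column — raw sums
across °C, ΔCp and Fréchet units would be dominated by whichever feature
has the largest numbers. The SCUCC baseline scores a curve by
c = ρ̄^P · p̄ with P = 1, where ρ̄ is the mean Pearson correlation with the
control reference curves and p̄ the mean two-sided normal tail probability
of the curve under the point-wise reference mean and sd; the
"average probability of membership" component is defined in the source
literature only by citation, so the normal-tail reading is an explicit,
documented surrogate. Its decision threshold is calibrated on the training
fold by maximising training F1 (midpoint candidates, smallest winner —
deterministic).

## The synthetic cohort generator

No thermogram cohort of this kind is publicly deposited, so the package
ships a seeded generator that emulates the study conditions: 70 subjects,
half cancer, curves on the 451-point grid. (The source description of the
grid is internally inconsistent — 1 °C increments versus a length of 451
over 45–90 °C; the 451-point/0.1 °C reading is used because 451 is stated
as the curve length, and the grid is configurable.) Each curve is a sum of
one or two Gaussian bumps with class-specific centres, widths and
amplitudes; independent per-subject jitter of each peak centre (the two
transitions reflect different protein fractions, so their locations are not
assumed to covary); a per-subject log-normal amplitude scale; a class-dependent probability of a single-peaked profile;
a class-dependent probability of an initially *decreasing* profile
(implemented as a decaying low-temperature shoulder — this is what makes IR
a real phenotype rather than a digitisation accident); i.i.d. Gaussian
measurement noise; and clipping at zero, since excess heat capacity is
reported nonnegative. Per-subject RNG substreams are derived from the root
seed by a counter, so subject i's curve is invariant to the cohort size.

The default class parameters encode a sparse disease signal: the dominant
transition shifts from 62.5 °C (control) to 66.5 °C (cancer) under 2 °C
per-subject jitter, and the negative-initial-response rate rises from 15 %
to 30 %; everything else — first-peak geometry, peak amplitudes, the 20 %
single-peak rate — is class-identical, so T1, PEAK1 and PEAK2 are
deliberately uninformative. Amplitudes are a few heat-capacity units (the
scale of published thermogram figures, and the scale at which the entropy
scheme's unit dependence behaves as reported); measurement noise sd is 0.3
and the subject-level amplitude scale sd 0.4. This
few-strong-features-among-noise relevance profile is the regime weighted
retrieval exists for, and the variance parameters put fold-average F1
around 0.6–0.8 — a genuinely hard problem, matching the premise that
these cohorts defeat average-pattern classifiers. The values were chosen
once, as a calibration, and are documented here rather than treated as
empirical claims. What the generator does *not* emulate:
instrument drift and baseline-subtraction artefacts, correlated
(smooth-in-temperature) noise, multimodal subpopulations within a class,
and any real biochemical coupling between peak positions and amplitudes.
Passing tests on synthetic cohorts therefore demonstrate correctness and
the stated qualitative behaviours of the algorithms, not clinical
performance on real plasma.

The published benchmark itself cannot be re-run without its (undeposited)
70-subject dataset. What the package does verify, via
`verify_reported_indices()`, is every arithmetic identity inside the
published result tables: each fold's F-1/G cell recomputed from its printed
precision/recall pair, and each summary cell recomputed from its fold
column. Because the printed inputs are rounded to 4 decimals, agreement is
assessed to one unit in the fourth decimal. Three published cells fail even
that: one G cell printed one unit low, and the K-NN G-measure AVG/STD
summary cells, which are inconsistent with their own fold column (the
printed AVG resembles the neighbouring F1 average). The checker reports
them as mismatches rather than papering over them.

## Numerical choices and degenerate inputs

* Dense ranks use exact floating-point equality; distances that differ in
  the last ulp are distinct ranks. This is deterministic, and with
  continuous features exact ties essentially only arise from genuinely
  identical inputs.
* Similarity ties at retrieval break by case insertion order (oldest
  first); prediction ties at even k go to control.
* Wilcoxon with every pooled value tied has zero null variance; p = 1.
* A zero-variance feature has entropy 0 (not an error); an all-zero
  entropy or Wald vector falls back to equal weights with a warning.
* SCUCC grid points with degenerate reference sd are skipped with a
  warning; if all points are degenerate the tail probability degrades to
  its zero-variance limit, an exact-match indicator.
* `information_indices()` maps zero denominators to 0 with a warning so
  fold summaries stay total.

## Problem sizes used in the shipped checks

The test suite exercises the exact oracles at the sizes where exhaustive
enumeration is feasible (curves of length ≤ 6 against a branch-and-bound
coupling enumeration; rank-sum groups of ≤ 6 against full permutation
enumeration), contract properties on ~1000 small randomised training sets,
and the full 70-subject, 451-point pipeline for the separable-cohort and
benchmark checks (the benchmark comparison averages 10 seeded replicates).
These sizes are the package's chosen trade-off between coverage and a test
run that stays pleasant to iterate on.

## Known limitations

* The discrete Fréchet distance is O(n·m) per pair; retrieval over a fold
  is the dominant cost of an experiment. The compiled kernel keeps a
  70-subject, 5-fold, all-models run under a minute, but cohorts of
  thousands of curves would want subsampled grids or banded couplings.
* Weight schemes assume exactly two classes; J > 2 is out of scope.
* The entropy scheme's unit dependence means ETCBR weights are not
  comparable across cohorts measured on different ΔCp scales.
* The SCUCC membership probability is a documented surrogate for an
  under-specified published definition; its absolute composite values
  should not be compared across studies.
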
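---
title: "Methods: quantifying lymph-node involvement from paired preclinical ultrasound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying lymph-node involvement from paired preclinical ultrasound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lnscore)
```

## The measurement problem

In small-animal models of metastatic cancer, the first node draining the
tumor site is the sentinel of spread. Because "normal size" is poorly
defined for mouse lymph nodes, the design this package implements is
*paired*: every subject contributes a tumor-draining (left) inguinal
node and an internal-control (right) node, and every criterion compares
left against right within the same animal. Five binary imaging signs
are read per subject and combined into a sum score that is then
evaluated against histopathology.

This vignette documents the models, the tunable parameters, the
numerical choices, and what the synthetic-data generator does and does
not emulate.

## Morphometry from contour stacks

A node's geometry arrives as a *contour stack*: one manually traced,
simple closed polygon per B-mode slice, acquired by a motorised sweep at
a uniform elevational step (default 0.038 mm, the finest step of the
acquisition hardware the design assumes).

**Volume** is the plain Cavalieri slab sum, spacing × Σ(shoelace slice
areas), with no end-cap correction. At 0.038 mm spacing on node-sized
convex bodies the discretisation error is far below 1% (the test suite
verifies < 1% against `4/3·π·abc` on a ten-shape ellipsoid grid, and
< 0.5% change under spacing halving), so a correction would add
complexity without measurable benefit.

**Length and width.** The length is the longest in-plane diameter over
all slices: per slice, the maximum vertex-pair chord, which is the
diameter of the convex hull and is found by rotating calipers (verified
against exhaustive O(n²) chord search). The width is measured in the
same slice as the breadth perpendicular to the length chord — the
maximal perpendicular component over all boundary point pairs,
equivalently the support width normal to the length axis. This is the
caliper measurement a reader makes on the 2D image: for a 4×1 mm
rectangle the length is the diagonal √17 ≈ 4.12 and the width is
8/√17 ≈ 1.94, the distance between the two supporting lines parallel
to the diagonal. (A literal "longest interior chord perpendicular to
the length chord" would give ≈ 1.03 for that rectangle, which is not
what any reader would report as the short axis; we use the support
width.) Roundness is the strict rule L/W < 2; a ratio of exactly 2 is
non-round.

```{r morpho-demo}
rect <- matrix(c(0, 0, 4, 0, 4, 1, 0, 1), ncol = 2, byrow = TRUE)
measure_stack(contour_stack(list(rect), spacing_mm = 0.038))
```

## Perfusion from bolus time-intensity curves

CEUS bolus kinetics are analysed from the mean ROI intensity over the
cine loop, with a mask of frames discarded by motion correction.
Excluded frames never enter any window, sum or fit.

1. **Quality gate.** A curve with more than 40% of frames excluded is
   unusable (the gate is inclusive at exactly 40%); its TTP and WiR are
   reported unavailable, and the subject's sum-score denominator
   shrinks accordingly.
2. **Baseline and arrival.** The baseline is the median over the first
   10% of non-excluded frames; its sd sets a detection threshold at
   baseline + 3 sd (configurable `k_sd`). The candidate onset is the
   earliest time the intensity stays above threshold for 3 consecutive
   non-excluded frames. Because a threshold crossing on a smoothly
   rising bolus is systematically late under noise, the arrival is
   refined by back-extrapolating a straight line through the early
   wash-in (from the last frame within 0.5 sd of baseline to just past
   the crossing) down to the baseline level. A flat curve raises a
   no-enhancement error.
3. **Bolus model.** The fit is `I(t) = I₀ + A·lognormal-density(t − t₀;
   μ, σ)` — the standard smooth unimodal model for first-pass bolus
   kinetics — by Levenberg–Marquardt least squares on the non-excluded
   samples, with at least five deterministic multi-starts around
   method-of-moments initial values. The onset `t₀` is refined within a
   bounded window during the fit ([−1.5 s, +0.3 s] around the detected
   arrival), with start offsets of up to −0.9 s, because the detected
   arrival carries a shape-dependent residual bias. The fit is
   deterministic given the curve.
4. **Parameters.** TTP is the mode of the fitted bolus relative to
   arrival, `exp(μ − σ²)`. WiR is the OLS slope of enhancement versus
   time over [arrival, peak], computed on the fitted curve sampled at
   the frame grid by default; a `raw` mode (slope on the raw
   non-excluded samples) is exposed because vendor software does not
   document which it uses — the two agree within ~10% at low noise.

**Identifiability note.** The shifted-lognormal model has a nearly flat
ridge trading `t₀` against `μ`: profiling the least squares over fixed
`t₀` at 10%-of-peak noise shows the global optimum wandering ±0.15 s.
This is a property of the likelihood geometry, not the optimiser, and
it bounds the achievable TTP precision for short-TTP, slow-toed curves.
At the noise level of the default synthetic cohort (~2% of peak) TTP
recovery is comfortably within a few percent; the test suite's
recovery checks therefore sample the study's two bolus shapes
(TTP 1.93 s and 4.01 s, σ = 0.5) across noise levels up to 10% of peak
rather than sitting at the worst corner only.

## Scoring

Each subject's left node is scored against its own right node
(thresholds live in one `pipeline_config()` object):

| parameter | rule for score 1 | default |
|---|---|---|
| volume | left/right volume ratio ≥ threshold (inclusive) | 5 |
| shape | left-node L/W ratio < cutoff (strict) | 2 |
| hilum | no echogenic hilum detected (observed flag) | — |
| ttp | left TTP > right TTP × (1 + margin) | margin 0.2 |
| wir | left WiR < right WiR × (1 − margin) | margin 0.2 |

With a single measurement per node, a within-animal significance test
for "significantly increased/reduced" is impossible; the relative
margin rule (20%, configurable) is this package's operational stand-in,
and the group-level paired t-test (`group_paired_ttest()`, left vs
right across subjects) is reported separately at cohort level without
gating any per-subject score. This is the largest interpretive choice
in the package and is deliberately surfaced rather than hidden.

The sum score counts positive parameters over the *available* ones:
unusable CEUS removes ttp and wir together, so a subject can be 3/3 =
100% on morphometry alone. Percentages are kept exact internally and
rounded (half away from zero) only for display.

## Diagnostic evaluation

Predictions are compared with pathology on the left nodes only (the
right nodes are internal controls, never evaluated). For each parameter
and for each sum-score threshold, the 2×2 confusion matrix yields
sensitivity, specificity, PPV, NPV and accuracy; any metric with a zero
denominator is *undefined* (`NA`, shown as `--`), never 0. Subjects
with an unavailable parameter are excluded from that parameter's matrix
only.

Confidence intervals are exact Clopper–Pearson in beta-quantile form,
chosen because exact intervals are the defensible default at n ≤ 8 and
because they reproduce every published bracket of the reference study;
the implementation is verified against brute-force inversion of the
binomial CDF to 1e-9 for all n ≤ 30 and achieves ≥ 95% empirical
coverage over 10,000 simulated binomials. One published cell disagrees
with exact computation: the upper bound of a 3/4 proportion is 0.9937 →
99, printed as 100 in the source table; `reproduce_study()` reports the
computed value and flags the cell.

At threshold 0 a subject is predicted positive only if its sum percent
is *strictly* positive; otherwise every subject would be positive and
specificity would be identically zero, contradicting the published
threshold-0 row. Thresholds are compared on exact fractions, not
rounded percentages.

```{r reproduce}
rs <- reproduce_study()
rs$report
rs$mismatches
```

## The synthetic cohort generator

`generate_cohort()` emulates the *statistical endpoint* of the paired
study, not its images:

- **Geometry**: each node is an axis-aligned ellipsoid sliced
  perpendicular to the elevational axis, with semiaxes solved from the
  latent volume and L/W ratio (a = q·b, c = 0.8·b), a small seeded
  multiplicative tracing jitter (sd 0.2%), and — when the hilum is
  visible — a wedge-shaped indent (depth 35%, ~34° half-width) carved
  into one long side of the central slices. The indent removes a few
  percent of volume and narrows the width slightly, so measured control
  nodes sit a little above their latent L/W ratio and measured volume
  ratios run a few percent above the latent target; this is the
  physical signature of the hilum, not an error.
- **Effect sizes** default to the reference study's endpoint values:
  volume ratio 9.92 (right volume 1.44 mm³), L/W 1.621 ± 0.181 involved
  vs 2.432 ± 0.166 control, hilum lost with probability 1 in involved
  nodes, TTP 4.01 ± 1.26 s vs 1.93 ± 0.77 s. Absolute wash-in rates are
  not published; 2.0 (control) vs 0.5 (involved) a.u./s were fixed once
  as a realistic ~4× reduction. Volume and WiR get lognormal
  between-animal variation (sdlog 0.25 and 0.3), the ratio itself sdlog
  0.15 — chosen once as realistic for endpoint cohorts of this size.
- **Bolus curves** are lognormal with σ = 0.5, amplitude solved so the
  clean curve's wash-in slope equals the node's latent WiR, baseline 1,
  20 Hz × 1000 frames, additive Gaussian noise (default sd 0.05 ≈ 2% of
  peak), and 5% of frames excluded uniformly at random (60% for the
  unusable-CEUS node, above the 0.4 gate).
- **Archetypes**: the last two tumor-group slots are two fixed
  phenotypes generated at exact group means without between-animal
  variation, because they emulate specific observed animals with known
  score patterns: `X4` (fully imaging-involved except a raised WiR,
  pathology negative → 4/5 = 80%) and `X5` (control-node CEUS unusable,
  pathology positive → 3/3 = 100%). The default 5 + 3 design therefore
  yields 8 subjects and 16 nodes.
- **Determinism**: all randomness flows from the single spec seed; the
  stream order is fixed (subjects in order, left before right, latent
  draws then per-node sub-seeds), so identical specs give
  byte-identical cohorts.

What the generator does **not** emulate: B-mode image content (no
speckle, no segmentation task — contours are given), longitudinal tumor
growth (endpoint sizes only), inter-injection carryover between the two
boluses, or pathology-reader variability. Passing tests on synthetic
cohorts therefore validate the estimators and the decision rule, not
image segmentation or acquisition physics.

## Problem sizes and runtime choices

The test suite and the acceptance script size their simulations to what
the estimators need, not more: 100-seed Monte-Carlos for arrival bias
and TTP/WiR recovery, a ten-shape ellipsoid grid at 0.038 mm spacing,
2000 replicates for the t-test type-I check, ~10,000 binomial draws for
interval coverage, an 8-subject end-to-end study and a 20-subject
cohort for group-mean recovery. A full cohort pipeline (16 nodes:
morphometry, 16 bolus fits, scoring, diagnostics) runs in a few seconds
on one core.

## Known limitations

- The margin rule for per-subject TTP/WiR positivity is a stated
  stand-in for an undescribed per-animal criterion; with margins far
  from the group effect sizes it will misclassify borderline nodes.
- TTP precision is bounded by the t₀–μ ridge of the shifted-lognormal
  model (± ~0.15 s at 10%-of-peak noise); short-TTP curves at high
  noise approach that bound.
- The Cavalieri estimator assumes the traced contours are in physical
  order at uniform spacing; it does not interpolate across missing
  slices.
- Width is defined as perpendicular support width; for strongly
  concave slices (beyond the modelled hilar indent) a support-based
  width can exceed any interior chord.
- The evaluation unit is the subject's left node; the package does not
  model correlation between parameters when interpreting the sum-score
  sweep, matching the source analysis.
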
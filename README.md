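# lnscore

Quantitative scoring of lymph-node (LN) metastatic involvement from
preclinical ultrasound, for imaging scientists working with paired
tumor-draining / control node designs in small-animal cancer models.

A draining LN that harbours metastases changes in predictable,
sonographically visible ways: it swells, becomes round, loses its
echogenic hilum, and its perfusion slows. `lnscore` turns those signs
into numbers and a decision rule:

- **Morphometry** from serial B-mode contour stacks (motorised 3D sweep,
  uniform slice spacing): Cavalieri volume
  `V = d · Σᵢ Aᵢ` (slice area times spacing), the longest in-plane
  diameter `L` (rotating-calipers convex-hull diameter), the
  perpendicular width `W` (breadth normal to the length chord in the same
  slice), and roundness `L/W < 2`.
- **Perfusion** from contrast-enhanced ultrasound (CEUS) bolus
  time–intensity curves with motion-excluded frames: baseline and
  contrast arrival `t₀` (threshold detection with back-extrapolation),
  a lognormal bolus fit
  `I(t) = I₀ + A · lnorm(t − t₀; μ, σ)`,
  time-to-peak `TTP = exp(μ − σ²)` and wash-in rate `WiR` (OLS slope of
  enhancement from arrival to peak).
- **Scoring** of each subject's left (tumor-draining) node against its
  own right (control) node, five binary parameters: volume ratio ≥ 5×,
  roundness, hilum loss, lengthened TTP, reduced WiR. The sum score is
  the positive count over the *available* parameters (an unusable CEUS
  acquisition shrinks the denominator instead of imputing zero).
- **Diagnostics** against histopathology: confusion counts, sensitivity,
  specificity, PPV, NPV and accuracy, each with an exact
  (Clopper–Pearson) 95% confidence interval, for every parameter and for
  a sum-score threshold sweep.
- **Synthetic cohorts**: a seeded generator producing paired contour
  stacks, bolus curves, hilum flags and pathology labels with the
  statistical structure of the reference eight-mouse study, so the whole
  pipeline is testable without any data download.

## Worked example

Reproduce the reference study's evaluation from the embedded score
matrix (five tumor-injected subjects M1–M5, three control-injected
MA–MC; M5's control-node CEUS was unusable, so its perfusion scores are
unavailable and its denominator is 3):

```r
library(lnscore)
rs <- reproduce_study()
rs$report
#>    variable n sensitivity  specificity  ppv          npv          accuracy
#> 1  volume   8 100 [40-100] 75 [19-99]   80 [28-99]   100 [29-100] 88 [47-100]
#> 2  shape    8 100 [40-100] 50 [7-93]    67 [22-96]   100 [16-100] 75 [35-97]
#> 3  hilum    8 100 [40-100] 75 [19-99]   80 [28-99]   100 [29-100] 88 [47-100]
#> 4  ttp      7 100 [29-100] 75 [19-99]   75 [19-99]   100 [29-100] 86 [42-100]
#> 5  wir      7 100 [29-100] 100 [40-100] 100 [29-100] 100 [40-100] 100 [59-100]
#> 6  sum_0    8 100 [40-100] 50 [7-93]    67 [22-96]   100 [16-100] 75 [35-97]
#> ...
#> 11 sum_100  8 100 [40-100] 100 [40-100] 100 [40-100] 100 [40-100] 100 [63-100]
rs$mismatches
#>    variable metric   computed   published matches
#> 14      ttp    ppv 75 [19-99] 75 [19-100]   FALSE
```

Each cell is `point [lower–upper]` in percent. WiR is the single best
individual parameter (all four metrics 100% on n = 7), and requiring all
available parameters to be positive (`sum_100`) gives perfect
classification on this cohort. The one `mismatches` row is the single
cell where exact computation disagrees with the published table: the
upper bound of a 3/4 PPV is 0.9937, which rounds to 99, not 100 — a
suspected typographical inconsistency in the source.

The same analysis runs end to end on synthetic data:

```r
coh <- generate_cohort(cohort_spec(seed = 42))   # 5 tumor + 3 control subjects
res <- run_pipeline(coh, pipeline_config(seed = 42))
res$scorecards[, c("subject_id", "sum_score", "available", "sum_percent")]
#>    subject_id sum_score available sum_percent
#> T1         T1         5         5         100
#> T2         T2         5         5         100
#> T3         T3         5         5         100
#> C1         C1         0         5           0
#> C2         C2         1         5          20
#> C3         C3         0         5           0
#> X4         X4         4         5          80
#> X5         X5         3         3         100
```

`X4` is the imaging-positive / pathology-negative archetype (everything
involved-looking except a *raised* wash-in rate, 4/5 = 80%); `X5` is the
missing-CEUS archetype (3/3 on the morphometric parameters alone).
Cohorts round-trip to plain CSV via `write_cohort()` / `load_cohort()`.

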
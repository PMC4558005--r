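---
title: "Calibrating walking-speed cut points from accelerometer counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating walking-speed cut points from accelerometer counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accelcal)
```

## The problem and the model

Activity monitors accumulate accelerations into an arbitrary unit,
*counts per epoch*, per axis and as a composite vector magnitude (VM).
Counts only become interpretable after calibration against a reference.
`accelcal` anchors the calibration in walking speed: participants walk
instructed three-minute bouts at self-selected slow, normal and brisk
pace over a measured indoor course (210-m laps here), speed is computed
as distance over duration, and the task is to find the count thresholds
that recover the speed category of a bout from its counts alone. This is
the design of choice for populations whose altered gait (the motivating
case is mild-to-moderate Parkinson's disease) makes cut points calibrated
on healthy adults inapplicable, and for whom walking speed itself is a
clinically meaningful quantity.

Three modelling commitments shape the pipeline:

* **Strata come from the sample, not from fixed speeds.** The LOW/MID
  boundary is the 75th percentile of the self-selected *slow* bout
  speeds; the MID/HIGH boundary the 25th percentile of the *brisk* bout
  speeds. Bouts are then labelled by measured speed, not by instruction:
  self-selection is noisy, and a "normal" bout walked slowly is evidence
  about slow walking. This restructuring is why the truth labels and the
  instructed conditions can disagree, and the package keeps such
  disagreements.
* **The bout is the unit of analysis.** Each bout is scored by its mean
  counts/15 s. Published stratum sizes in this design count bouts, not
  epochs; epochs within a bout are strongly dependent (same walk, same
  participant), so treating them as units would overstate the effective
  sample. Epoch-level scoring can be emulated by passing epoch rows as
  bouts, but it is not the default.
* **Cut-point selection is deterministic.** The originating practice of
  visually inspecting ROC coordinates is not reproducible. The package
  replaces it with a lexicographic rule: among coordinates whose
  non-priority metric is at least a floor (default 0.60), maximise the
  priority metric (sensitivity for the low cut, specificity for the high
  cut), break ties by the other metric, then by distance to the midpoint
  of the two class medians, then by the smaller threshold. The floor of
  0.60 sits just below the smallest operating value one would accept in
  this design; it is a configurable parameter, not a fitted one.

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| `epoch_length_s` | 15 | s | summarisation window; 15 s catches short activity bursts a 1-min epoch averages away |
| percentile pair | 75th of slow, 25th of brisk | — | stratum boundaries; interior percentiles keep the boundary inside the data |
| `floor_other` | 0.60 | proportion | admissibility floor for the non-priority ROC metric |
| `trim_epochs` | 0 | epochs | optional trimming of gait initiation/termination per bout end |
| `boot` | 2000 | replicates | participant-level bootstrap for the κ CI |

Percentiles use the weighted-average, (n+1)-based definition
(`stats::quantile` type 6), the default of the statistical software
traditionally used for such analyses; the choice matters at these sample
sizes and is therefore fixed and documented rather than silently
platform-dependent.

## Integer cuts versus exact thresholds

Cut points are reported as integers — floor of the selected threshold for
the low cut (`LOW iff counts ≤ low_cut`), ceiling for the high cut — so
the intermediate class is the complementary integer interval
`[low_cut + 1, high_cut − 1]`, matching how such thresholds are printed
and used on integer device counts. On integer counts the integer rule
and the exact rule coincide (`s ≤ floor(t)` iff `s ≤ t` for integer
`s`). Bout *means*, however, are real-valued, and flooring would silently
reclassify a bout lying exactly at the selected threshold. The
`cutpoint_set` therefore carries both: integer cuts for reporting, and
the exact selected thresholds, which `classify_counts()` uses when given
the full object. Rounding, here as everywhere in the package, is a
display convention (half-up, two decimals for speeds), never part of the
computation.

## AUC and agreement statistics

AUC is computed as the Mann–Whitney probability that a positive bout
beats a negative bout in the direction of the test, ties counted one
half; this equals the trapezoidal area under the empirical ROC curve and
is tested against it. The 95% CI uses the Hanley–McNeil closed-form
standard error: at 30-participant scale it is adequate, closed-form, and
keeps the dependency surface small; DeLong-style resampling adds little
here because the CI is descriptive, not inferential.

Validation pools leave-one-out folds into a 3×3 confusion matrix.
Absolute agreement is the trace proportion. Quadratic weighted Cohen's κ
uses weights `w_ij = 1 − (i−j)²/(k−1)²`, so a bout misclassified into
the adjacent stratum costs a quarter of a two-stratum error; for two
categories the weights reduce κ to the unweighted statistic (a tested
identity). The κ CI is a percentile bootstrap over *participants*, not
bouts: a participant's bouts share a random intercept and a fold, and
resampling the independent sampling units is the only resampling scheme
that respects that clustering. The asymptotic SE for weighted κ assumes
independent classifications and would be anti-conservative here.

Two further choices in the cross-validation:

* **Speed thresholds are computed once on the full sample and held fixed
  across folds.** The stratification defines the *reference* being
  predicted; re-deriving it per fold would make each fold validate
  against a different ground truth. A `strict = TRUE` mode recomputes
  the percentiles per training fold (relabelling training bouts only)
  for sensitivity analysis.
* **Degenerate folds are skipped, not fatal.** If removing a participant
  empties a training stratum or crosses the cuts, the fold is recorded
  and skipped with a warning, and the report states how many folds
  contributed.

## What the synthetic cohort emulates — and what it does not

The generator reproduces the statistical skeleton of the hallway
protocol: per-condition speed distributions with means 0.89/1.17/1.47 m/s
and SDs 0.11/0.08/0.14, a shared participant pace shift (SD 0.06 m/s) so
condition ordering is violated only rarely, bouts covering whole 210-m
laps for ≥ 180 s (hence ≥ 12 complete epochs), and counts from a linear
mean model fitted through the three published (stratum speed, stratum
counts) points — slope ≈ 969 (vertical) and ≈ 834 (VM) counts/15 s per
m/s — with a participant random intercept, epoch noise, rectification at
zero, and a 2% missing-bout rate. Between- and within-participant
variance are not separable from stratum tables; the residual stratum
variance (after removing the slope-mediated speed-spread component) is
split 50/50 between the two, a flagged, configurable convention. The VM
signal is floored at the vertical count and the residual magnitude split
equally across the two horizontal axes, so the epoch-level identity
`vm = sqrt(v² + ap² + ml²)` holds exactly.

The generator does **not** emulate raw 30-Hz accelerations, tremor,
freezing-of-gait or dyskinesia artifacts, device filtering, non-wear, or
any nonlinearity in the count–speed relation. Passing tests on synthetic
cohorts therefore demonstrate that the *procedure* recovers a known
generative structure — not that any particular cut points transfer to
real devices or real gait. With noise at the published spread, simulated
cohorts yield vertical-axis cuts broadly in the published neighbourhood,
which is a plausibility check, nothing more: the published values depend
on the raw study data, which is not deposited.

## Numerical and degenerate-input conventions

* Trailing partial epochs are dropped (configurable), not zero-padded:
  padding biases bout means downward.
* Counts are accepted as non-negative reals; device exports with float
  VM columns parse unchanged, and integers round-trip bit-identically
  through the CSV dialects.
* `t_low ≥ t_high` ("strata collapse"), single-class ROC input, crossed
  cuts, and empty confusion matrices are errors with specific messages,
  not silent results.
* Weighted κ with all mass in one diagonal cell is 1 by convention
  (observed and expected agreement both saturate).
* The truncated-at-0.3 m/s speed draw guards against non-physical bouts
  at extreme random draws; rectification of counts at zero matches how
  count registers behave.

## Problem sizes used by the test suite

Unit tests run on cohorts of 4–12 participants; the distributional
convergence check uses one 200-participant cohort; the recovery
experiment runs 50 replicates of 30-participant cohorts at each of three
noise scales (0.25×, 0.5×, 1×) with point-κ leave-one-out validation;
the acceptance script uses the default 30-participant design with 2000
bootstrap replicates. These sizes make the whole suite run in about a
minute while keeping every assertion at the design's natural scale.

## Known limitations

* Cut points are device- and placement-specific by construction; the
  package calibrates whatever counts it is given and cannot remove that
  dependence.
* The Hanley–McNeil CI ignores the within-participant clustering of
  bouts (three bouts per participant enter one ROC); the κ CI respects
  clustering, the AUC CI does not.
* With continuously distributed speeds, the percentile boundaries fall
  inside dense regions of the data, so leave-one-out validation of the
  boundary participants is intrinsically hard: even a noiseless cohort
  misclassifies the bout nearest each boundary when its owner is held
  out. This is a property of the design, not of the implementation, and
  it bounds attainable agreement slightly below 1 in realistic cohorts.
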
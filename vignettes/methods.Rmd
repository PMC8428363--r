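---
title: "Methods: synthetic data, scoring, and statistics in PTENpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic data, scoring, and statistics in PTENpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PTENpipe)
```

PTENpipe automates the scoring of PTEN protein status on
immunohistochemically (IHC) stained prostate tissue slides and the
downstream prognostic statistics. This vignette documents the scientific
model behind each stage, the package's parameter defaults and the reasoning
behind them, the numerical methods, and the known limitations of the
synthetic data used for validation.

## Pipeline overview

A whole-slide image is partitioned into non-overlapping 800 x 800-pixel
tiles (remainder margins are dropped). Each tile is labeled tumor or
non-tumor — either from pathologist polygon annotations (a tile is a tumor
tile when its center lies inside a tumor polygon, boundary-inclusive) or by
a trained tile classifier. Within tumor tiles, cells are detected,
segmented, and assigned to four classes: tumor PTEN-positive, tumor
PTEN-negative, non-tumor PTEN-positive, non-tumor PTEN-negative. The PTEN
score of a slide is

$$\mathrm{score} = \frac{n_\text{tumor+}}{n_\text{tumor+} + n_\text{tumor-}},$$

undefined (`NA`) when the slide yields no tumor cells. A patient's score is
the unweighted mean of their defined slide scores; it is dichotomized at
50% (PTEN-low strictly below, PTEN-high at or above). PTEN status is
combined with DNA ploidy (non-diploid = tetraploid or aneuploid) into a
three-level marker (both-favorable / one-adverse / both-adverse) and
integrated into the CAPRA-S score by adding one point per adverse marker
(risk groups: Low 0–2, Intermediate 3–5, High >= 6).

## Synthetic slides

Real IHC slides and trained network weights are not distributable, so the
package ships a seeded slide generator (`slideSpec()`, `generateSlide()`)
that plants a complete ground truth: tumor polygons, per-cell classes, and
a pixel-level instance mask.

Rendering uses Beer–Lambert composition of two stain optical densities
with the Ruifrok–Johnston H-DAB basis: hematoxylin marks all nuclei, DAB
marks PTEN-positive cells (nuclear signal plus a perinuclear ring,
mimicking cytoplasmic staining). Cell nuclei are perturbed ellipses; tumor
nuclei are planted larger (semi-major axis 6.5–9.5 px) than non-tumor
nuclei (4–5.8 px) so that morphology, not only stain, separates the
classes.

Key parameters and their rationale:

* `mpp = 0.227` — microns per pixel of the reference scanner setting.
* `tumorCellDensity = 60`, `nontumorCellDensity = 40` cells per tile —
  sparse enough that watershed segmentation is near-exact, dense enough for
  stable per-tile statistics.
* `nontumorPositiveFraction = 0.9` — PTEN is retained in benign tissue,
  which acts as an internal staining control.
* `failureMode` — `"low_antibody"` attenuates and `"no_antibody"` removes
  the DAB channel, modeling staining failures; failure slides are flagged
  in the ground truth but *not* withheld from the automatic pipeline,
  because the automated scoring applies no staining quality control.
* Cells are placed on a jittered grid with a 12-px margin from image
  borders and tile-grid lines, so every nucleus lies in exactly one tile.
  This is a deliberate simplification: it makes tile-level pooling exactly
  conserve the planted cell counts, which in turn makes end-to-end
  exact-recovery tests well-defined.

Realism limits: no scanner artifacts, no overlapping or split nuclei, no
stain variation between slides, rectangle-like tumor regions. The
generator validates detector *logic* (ranking, matching, pooling,
arithmetic), not detector *difficulty*.

```{r slide-example}
s <- generateSlide(slideSpec(widthPx = 800, heightPx = 800,
                             nTumorRegions = 1, tumorRegionCover = "full",
                             positiveFraction = 0.6, tumorCellDensity = 150,
                             seed = 7), slideId = "demo")
plantedScore(s$truth)
table(cells(s$truth)$class)
```

## Reference backends

The production-scale system described in the source methodology uses
convolutional networks; those weights and training data are unavailable,
so the package's reference backends are deterministic classical methods
behind the same interfaces (a CNN backend can be substituted without
changing any downstream code):

* **Tumor-tile detector** (`trainTileClassifier()`): per-tile stain and
  texture features (hematoxylin/DAB channel moments and coverage, nuclear
  blob counts and areas) with a linear discriminant. Features are
  standardized and near-collinear features (|r| >= 0.95 on the training
  matrix) pruned before fitting: with few training tiles the pooled
  covariance is otherwise near-singular and the discriminant weights
  explode, extrapolating wildly outside the training range. The decision
  threshold on the tumor posterior defaults to 0.5.
* **Cell detector/classifier** (`trainCellModel()`, `detectCells()`):
  nuclei are segmented on the smoothed hematoxylin density channel
  (threshold 0.35 OD, hole filling, watershed on the distance map,
  minimum area 15 px), then two linear discriminants classify each
  instance — tumor vs non-tumor on size/shape/hematoxylin features, and
  PTEN-positive vs negative on nuclear and perinuclear DAB density.
  Overlapping proposals are resolved by confidence-ranked non-maximum
  suppression at IoU 0.5.
* **Oracle backend** (`oracleCellModel()`): emits the planted ground truth
  as detections, isolating the scoring and statistics stages from detector
  quality.

Detection quality is evaluated with mean average precision
(`meanAveragePrecision()`): per class, detections are ranked by confidence
and matched greedily to free ground-truth instances (highest IoU, IoU >=
0.5, each truth consumed once); AP uses all-point interpolation (the
precision envelope), and mAP averages over classes present in the truth.
`refineAnnotations()` implements the iterative annotation protocol:
detections unmatched by any existing annotation (IoU below threshold) are
routed to a reviewer and merged back, so the annotation set never shrinks.

## Synthetic cohorts

`generateCohort()` simulates a surgical cohort with known effect sizes:

* True patient PTEN scores: PTEN-low patients draw scores from
  0.5·Beta(2,2) (all below the 0.5 threshold), PTEN-high from
  0.5 + 0.5·Beta(2,2). Manual and automated scores are the truth plus
  N(0, `scoreNoiseSd` = 0.04), clamped to [0, 1].
* Event times are exponential with proportional hazards. Two effect
  models: `"additive"` (default log-HRs log 3.32 for PTEN-low and log 1.98
  for non-diploid) and `"combined"` (log 1.94 one-adverse, log 4.63
  both-adverse vs both-favorable). These generating values are simulation
  presets, not claims about any real cohort.
* `baselineHazard = 0.02`/year — calibrated so the default 259-patient
  cohort yields roughly a 27% biochemical-recurrence fraction over 10
  years of follow-up, matching the event fraction of the motivating
  validation cohort size.
* PSA follow-up: quarterly visits (`psaVisitIntervalYears = 0.25`) with a
  per-patient random schedule offset of runif(0.5, 1.5) x interval.
  Staggering matters: a single shared visit grid produces massive
  event-time ties, and tie-approximate Cox fits then systematically
  attenuate the recovered hazard ratios.
* Biochemical recurrence (`deriveBcr()`) is the first post-operative PSA
  >= 0.4 ng/mL (boundary-inclusive); patients never reaching it are
  censored at their last registration. The simulated post-recurrence PSA
  level (`psaRecurrenceLevel = 0.5`) is validated to be at least 0.4 so
  that every latent event is observable at the next visit.

```{r cohort-example}
coh <- generateCohort(cohortParams(nPatients = 259, seed = 1))
outc <- deriveBcrCohort(coh$psa)
mean(outc$event) # event fraction near 27%
```

## Statistical methods

* **Kaplan–Meier / log-rank / Cox**: computed with the `survival` package.
  Cox fits use the Efron tie approximation (the method is unstated in the
  motivating analysis; Efron is the better approximation and the
  `survival` default). Hazard-ratio CIs are Wald intervals; each covariate
  term additionally gets a (multi-df) Wald chi-square test. Non-convergence
  (for example complete separation in a nearly empty stratum) is flagged
  via `converged` and a warning, never silently.
* **Harrell's c-index** (`harrellCindex()`): `survival::concordance()`
  with `reverse = TRUE`; tied scores count 0.5. Verified in the test suite
  against an exhaustive pairwise-counting oracle.
* **ROC AUC** (`rocAuc()`): `pROC`, equal to the normalized Mann–Whitney
  statistic.
* **BCa bootstrap** (`bcaCi()`): hand-implemented bias-corrected and
  accelerated percentile interval — z0 from the tie-adjusted proportion of
  replicates below the estimate, acceleration from jackknife skewness,
  endpoints as type-6 quantiles at the adjusted probabilities. The
  resampling unit is the patient; `strata` resamples within strata (used
  by the AUC CI to hold class counts fixed). The reference analysis uses
  B = 10,000 replicates; examples here use fewer for speed. Cross-checked
  against `boot::boot.ci` in the test suite.
* **Concordance-difference test** (`cindexDifferenceTest()`): paired
  patient bootstrap of the c-index difference; the two-sided p-value is
  one minus the confidence level of the largest BCa interval excluding
  zero, located by bisection to 1e-4. By construction p < 0.05 exactly
  when the 95% BCa interval excludes zero.
* **Pearson correlation**: Fisher-z interval via `cor.test`.

```{r stats-example}
d <- merge(coh$patients, outc, by = "patient")
cf <- coxFit(d$time, d$event,
             data.frame(pten_low = d$pten_low_true,
                        nondiploid = d$ploidy != "diploid"))
cf$coefficients
```

## Cohort assembly and orchestration

`applyExclusions()` filters a patient roster with named rules
(`missing_consent`, `short_followup`, `no_tumor_material`,
`preoperative_therapy`, `postoperative_death`, `lost_followup`), reporting
per-rule counts; a patient triggering several rules is excluded once but
counted under each. `runPipeline()` orchestrates the full run from a
`pipelineConfig()` and is bit-reproducible for a fixed config: every
stochastic stage derives its seed from the config seed.

## Problem sizes and runtime

Slide generation and reference-backend training on 800 x 800 tiles take a
few seconds per tile on one CPU. The full test suite (including 100
replicate cohort simulations at n = 2000 and 1000 bootstrap-coverage
replicates) runs in a few minutes. `bcaCi` with B = 10,000 on a
259-patient cohort statistic takes on the order of a minute.

## Limitations

* Synthetic slides are far easier than real histology; reference-backend
  accuracies on them say nothing about CNN performance on tissue.
* The annotation inventory (`annotationInventory()`) records the
  development-study resource accounting; it is descriptive, not
  recomputable from shipped data.
* CAPRA-S base scores are an input column; computing them from
  clinicopathological components is out of scope.
* Manual-score consensus procedures and staining QC for manual reads are
  human procedures and are not modeled.
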
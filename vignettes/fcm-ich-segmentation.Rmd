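---
title: "Fuzzy C-means segmentation of ICH brain CT: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy C-means segmentation of ICH brain CT: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcmseg)
```

## The problem

Non-contrast head CT is the first-line examination in acute intracerebral
hemorrhage (ICH). Two quantities drive early management: the hematoma volume
and its change between the initial scan (within 6 h of onset) and the
re-examination at 24 h. Growth of at least 12.5 mL, or more than 33 %
relative to baseline, is the widely used *hematoma enlargement* criterion
and carries prognostic weight. Delineating the hyperdense bleed (and the
hypodense perihematomal edema around it) by hand is slow and
reader-dependent, which motivates intensity-based intelligent segmentation.

This package implements that pipeline around a fuzzy C-means (FCM) core and
validates every stage against a synthetic CT phantom with known ground
truth.

## The FCM model

Given samples $u_z \in \mathbb{R}^p$ (here $p = 1$: voxel intensity in
Hounsfield units), $Q$ cluster centres $b_s$ and a fuzzifier $n > 1$, FCM
minimises

$$ J(\mu, b) \;=\; \sum_{s=1}^{Q} \sum_{z=1}^{w} \mu_{zs}^{\,n}\,
   \lVert u_z - b_s \rVert^2, \qquad
   \mu_{zs} \in [0,1], \quad \sum_{s} \mu_{zs} = 1 .$$

Alternating the two stationarity conditions gives the classical updates

$$ b_s = \frac{\sum_z \mu_{zs}^{\,n} u_z}{\sum_z \mu_{zs}^{\,n}},
   \qquad
   \mu_{zs} = \Bigl[ \sum_{W=1}^{Q}
     \bigl( d_{zs} / d_{zW} \bigr)^{2/(n-1)} \Bigr]^{-1}, $$

with $d_{zs} = \lVert u_z - b_s \rVert$. Each update minimises $J$ exactly
in its block, so the objective trace is non-increasing — a property the test
suite asserts on randomised problems. Crisp labels come from the maximum
membership (ties to the lowest cluster index, for determinism).

Assumptions worth stating: FCM uses intensity only — no spatial coupling,
no atlas prior. It works here because acute blood (≈ 50–90 HU) is well
separated from parenchyma (≈ 25–40 HU); it is known to be noise-sensitive,
which the phantom suite quantifies directly (see the monotone-difficulty
test over noise levels 2–16 HU).

### Numerical choices

* **Fuzzifier** `n = 2`, the universal FCM default; configurable, with
  `n = 1` rejected outright (the membership exponent $2/(n-1)$ diverges).
* **Initialization** defaults to *quantile centres*: centre $s$ seeds at the
  $(s - 0.5)/Q$ sample quantile of each feature. This is deterministic,
  reproducible, and starts the clusters in ascending intensity order, which
  stabilises the cluster-to-tissue mapping. If two sample quantiles coincide
  (heavily discrete data, e.g. a noise-free phantom), the quantiles of the
  distinct values are used instead, which are strictly increasing whenever
  at least $Q$ distinct values exist. A seeded random-membership mode is
  available.
* **Convergence** on the maximum absolute membership change,
  `tol = 1e-5`, capped at `max_iter = 300`.
* **Zero distances**: the membership formula divides by zero when a sample
  sits on a centre. The analytic limit is crisp membership, split equally
  among coincident centres; all other distances are floored at `1e-12`
  before the ratio to avoid overflow.
* **Empty cluster**: a zero membership column raises a classed
  `degenerate-cluster` error (naming the cluster) instead of silent
  re-seeding, so pathological configurations surface in tests.

## CT pipeline

`segment_ich()` chains four stages:

1. **Brain extraction** on the raw volume: keep voxels in (−200, 200) HU,
   take the largest 26-connected 3-D component, fill in-plane holes. This is
   phantom-grade; it is not a radiology-grade skull stripper.
2. **Windowing** to the 0–100 HU brain window, so clustering sees
   soft-tissue contrast only.
3. **FCM clustering** of the pooled in-mask 3-D intensity set (FCM has no
   spatial term, so pooling only widens the intensity sample; a per-slice
   mode exists behind a flag). With the default `Q = 4` the classes, in
   ascending centre order, are `csf_low`, `edema_candidate`, `parenchyma`,
   `hematoma`: on non-contrast CT, perihematomal edema (≈ 10–20 HU) is
   *hypodense* relative to parenchyma, and acute hematoma is the most
   hyperdense soft tissue, so sorting fitted centres is a reliable
   tissue-naming rule regardless of the arbitrary cluster indices.
4. **Mask extraction.** Hematoma: voxels of the top class, components below
   50 voxels dropped (26-connectivity), largest component kept; an absent
   hematoma class yields an empty, flagged mask rather than an error.
   Edema: there is no standard closed rule for edema extraction from plain
   CT, so a documented heuristic is used — `edema_candidate` voxels within a
   10 mm anisotropy-aware dilation ring of the hematoma. The ring dilation
   is an ellipsoidal structuring element in physical mm (so 6 mm slices are
   respected), evaluated exactly via FFT convolution.

Arrays are indexed `(z, y, x)`; NIfTI I/O permutes to the on-disk
`(x, y, z)` order and carries spacing through `pixdim`.

## The phantom: what it emulates, what it does not

`generate_phantom()` builds a nested-ellipsoid head model on the default
16 × 96 × 96 grid at (6, 0.5, 0.5) mm — the slice thickness of routine
16-slice head CT. Tissues are painted at fixed attenuations (air −1000,
CSF 8, edema 14, parenchyma 30, hematoma 70 HU), blurred in-plane with a
0.6-voxel Gaussian as a partial-volume surrogate, then corrupted with
additive Gaussian noise (default sd 4 HU). Truth masks come from the
pre-blur geometry; truth volumes are reported both voxelized and analytic
($\tfrac43 \pi abc$).

Geometry defaults are the package's own choice at realistic scale for this
grid: brain semi-axes (42, 22, 22) mm with a 2.5 mm peripheral CSF rim
(subarachnoid surrogate), a central hematoma of semi-axes (15, 10, 10) mm
(≈ 6.3 mL, a typical ICH), and a 6 mm edema shell.

The phantom exercises exactly the failure modes FCM has — overlapping class
intensities under noise and partial volume — and nothing else. It does
**not** model skull and beam hardening, streaks, anatomical texture,
irregular hematoma shape, intraventricular extension, or scanner-specific
noise correlation. Passing the phantom suite therefore demonstrates correct
algorithmic behaviour under controlled contrast, not clinical-grade
performance on real scans.

One consequence is worth making explicit: with CSF at 8 HU and edema at
14 HU under sd 4 noise, the Bayes-optimal voxelwise 4-class accuracy is
≈ 0.90 — those two classes genuinely overlap. The tests therefore score the
labelling against a Bayes ceiling computed by an independent oracle rather
than against an arbitrary flat accuracy target; the hematoma class, 10 sd
away from its neighbour, is unaffected.

## Volumetry and enlargement

Volumes are voxel counts times the voxel volume. The enlargement verdict
uses `delta >= 12.5 mL` (inclusive, "by 12.5 mL") **or**
`delta / baseline > 0.33` (strict, "over 33 %"). *Relative edema volume* is
reported as the edema/hematoma ratio at a single timepoint — reported
group levels near 0.9–1.0 are consistent with this reading — with a
cross-timepoint mode (follow-up/baseline edema ratio) selectable, since the
literature does not pin the definition down.

## Longitudinal pairs and the cohort generator

`generate_longitudinal_pair()` scales the follow-up hematoma semi-axes by
$g^{1/3}$ so truth volume scales by $g$, and re-derives the edema shell.
`generate_cohort()` emits a 150-case table (48 enlargers / 102 controls by
default) with per-case size scales, growth factors, noise seeds, truth
volumes and labels; labels are validated against `classify_enlargement()`
re-applied to the truth volumes at construction. Growth factors are drawn
from uniform(1.45, 2.2) for enlargers and uniform(0.85, 1.18) for controls —
a deliberate > 5 % margin around the 33 % threshold so that voxelization
error cannot flip a truth label (ranges violating the margin are rejected).
Covariates use group presets: blood-pressure, ALC, NLR and HGB differences
and elevated blend/low-density/island sign incidences in the enlargement
group, with the satellite sign null; a `"null"` preset removes every group
difference for calibration studies. The preset serology levels are quoted
in their reported nominal unit of $10^9$/L even where that unit is
dimensionally odd (NLR is a ratio); they are generator presets, not
endorsed physiology.

## Cohort statistics

Continuous indexes use the two-sample *t* test — pooled-variance Student
form by default, matching the convention of two-group clinical tables, with
Welch behind a flag. Binary CT signs use the Pearson $\chi^2$ test on the
2 × 2 table without continuity correction by default (Yates behind a flag).
Significance is flagged per test at $\alpha = 0.05$ with no multiplicity
adjustment by default (Bonferroni/BH available), again matching the
reporting convention the panel mirrors. Under the null preset, both tests
hold their nominal size: the suite checks the empirical rejection rate over
1000 simulated cohorts against the binomial 99 % band around 0.05.

## Problem sizes used in the shipped checks

The test and acceptance runs use the default phantom grid (16 × 96 × 96,
≈ 56 000 in-brain voxels per case): 50 phantom cases for the headline
metric levels, 20 seeds per noise level for the noise-robustness curve on a
reduced 10 × 64 × 64 grid, 24 longitudinal pairs for verdict agreement, 20
replicates for mixture-mean recovery, and 1000 replicates for test-size
calibration. These sizes put each suite's Monte-Carlo error well inside the
margins being asserted while keeping a full run to a few minutes on one
CPU.

## A worked example

```{r example, eval = FALSE}
p <- generate_phantom(phantom_config(seed = 1))
seg <- segment_ich(p$volume)
evaluate_segmentation(p$truth_hematoma, seg$hematoma, seg$brain_mask)
volume_report(seg$hematoma, seg$edema, spacing = p$volume$spacing)

pair <- generate_longitudinal_pair(phantom_config(), growth_factor = 1.5, seed = 2)
segs <- lapply(list(pair$baseline, pair$followup), function(ph) segment_ich(ph$volume))
compare_timepoints(
  volume_report(segs[[1]]$hematoma, segs[[1]]$edema, pair$baseline$volume$spacing),
  volume_report(segs[[2]]$hematoma, segs[[2]]$edema, pair$followup$volume$spacing)
)
```

## Known limitations

* Intensity-only clustering: anything isodense with blood (dense calcium
  after windowing, partial-volume skull remnants on real scans) would join
  the hematoma class; the size filter and largest-component rule are the
  only spatial defences.
* The edema ring rule cannot find edema detached from the hematoma, and its
  10 mm radius is a tunable, not a learned, quantity.
* The brain extractor presumes the skull has already been excluded by the
  bone threshold; it is not validated on real skull-bearing CT.
* Enlargement verdicts inherit segmentation bias at both timepoints; near
  the 33 % boundary, verdicts flip more easily than far from it (the cohort
  generator deliberately avoids that boundary).
* The phantom's realism limits are listed above; no claim is made about
  performance on real clinical scans or external training datasets.
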
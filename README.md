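# fcmseg

Fuzzy C-means (FCM) segmentation and volumetry of non-contrast brain CT in
intracerebral hemorrhage (ICH).

Acute ICH management hinges on two CT-derived quantities: the hematoma
volume and its change between the initial scan (within 6 h of onset) and
the 24 h re-examination. Growth of **≥ 12.5 mL or > 33 %** is the standard
*hematoma enlargement* criterion and predicts poor outcome. This package is
for imaging researchers who want a tested, fully reproducible reference
pipeline for that measurement chain: intensity-based soft clustering of CT
voxels into tissue classes, hematoma and perihematomal-edema mask
extraction, overlap quality metrics, volumetry with the enlargement
verdict, and two-group cohort statistics — all validated against a built-in
synthetic phantom with known ground truth, so no clinical data is needed to
run anything.

## The model

FCM assigns each voxel intensity $u_z$ a membership $\mu_{zs} \in [0,1]$ in
every cluster $s$ (rows summing to 1) and minimises

$$J(\mu, b) = \sum_{s=1}^{Q}\sum_{z=1}^{w} \mu_{zs}^{\,n}\,\lVert u_z - b_s\rVert^2$$

by alternating the closed-form updates
$b_s = \sum_z \mu_{zs}^n u_z / \sum_z \mu_{zs}^n$ and
$\mu_{zs} = [\sum_W (d_{zs}/d_{zW})^{2/(n-1)}]^{-1}$ until memberships
stabilise; crisp labels take the maximum membership. With $Q = 4$ classes
sorted by fitted centre intensity, the most hyperdense class is the
hematoma candidate (acute blood ≈ 50–90 HU vs parenchyma ≈ 25–40 HU) and
the second-lowest is the edema candidate. Segmentations are scored with
sensitivity $|a \cap b|/|a|$, specificity $|c \cap d|/|c|$ and Dice
$2|a \cap b|/(|a|+|b|)$, computed inside the brain mask.

See `vignettes/fcm-ich-segmentation.Rmd` for the full methods account,
parameter rationale and limitations.

## Worked example

```r
library(fcmseg)

p   <- generate_phantom(phantom_config(seed = 1))   # 16 x 96 x 96, noise sd 4 HU
seg <- segment_ich(p$volume)                        # brain mask -> FCM -> masks

evaluate_segmentation(p$truth_hematoma, seg$hematoma, seg$brain_mask)
#> sensitivity 0.9973 | specificity 1.0000 | dice 0.9986
#> counts: |a| = 4040, |b| = 4029, |a n b| = 4029, |c n d| = 51712 (domain 55752)

volume_report(seg$hematoma, seg$edema, spacing = p$volume$spacing)
#> hematoma 6.04 mL | edema 14.35 mL | relative edema 2.375
```

The predicted hematoma volume (6.04 mL) recovers the phantom's voxelized
truth (6.06 mL) to within half a percent; Dice 0.9986 says the masks
overlap almost voxel-for-voxel inside the brain.

Two-timepoint comparison on a pair whose hematoma truly grows by 50 %:

```r
pair <- generate_longitudinal_pair(phantom_config(), growth_factor = 1.5, seed = 2)
segs <- lapply(list(pair$baseline, pair$followup), function(ph) segment_ich(ph$volume))
compare_timepoints(
  volume_report(segs[[1]]$hematoma, segs[[1]]$edema, pair$baseline$volume$spacing),
  volume_report(segs[[2]]$hematoma, segs[[2]]$edema, pair$followup$volume$spacing)
)
#> hematoma: 6.03 -> 9.44 mL (delta +3.41 mL, +56.6%)
#> edema:    14.28 -> 19.43 mL (delta +5.15 mL)
#> enlargement (>= 12.5 mL or > 33%): YES
```

The measured +56.6 % clears the 33 % branch of the criterion, matching the
generator's truth label.

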
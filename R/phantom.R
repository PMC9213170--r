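# Synthetic CT phantom and cohort generator.
#
# The phantom is a nested-ellipsoid head model on an anisotropic grid
# matching routine head CT (6 mm slices, 0.5 mm in-plane pixels): a brain
# ellipsoid with a thin peripheral CSF rim (subarachnoid-space surrogate),
# an ellipsoidal acute hematoma, and a hypodense perihematomal edema shell
# of fixed width around it. Tissue attenuations are standard CT densitometry
# values: air -1000 HU, CSF 8 HU, edema 14 HU, parenchyma 30 HU, acute
# hematoma 70 HU. Image formation is: paint tissue means, in-plane Gaussian
# blur (partial-volume surrogate), then additive Gaussian noise. Ground-truth
# masks come from the pre-blur, pre-noise geometry, so every downstream
# module can be scored against known truth.

#' Phantom configuration
#'
#' @param grid Grid size `c(nz, ny, nx)` in voxels.
#' @param spacing Voxel spacing `c(dz, dy, dx)` in mm (6 mm slices by
#'   default, matching 16-slice spiral head CT acquisition).
#' @param hu Named tissue attenuations in HU; must contain `air`, `csf`,
#'   `edema`, `parenchyma`, `hematoma` with `edema < parenchyma < hematoma`.
#' @param noise_sd Additive Gaussian noise SD in HU (default 4).
#' @param blur_sd In-plane Gaussian blur SD in voxels (default 0.6); 0
#'   disables blurring.
#' @param brain_semiaxes_mm Brain ellipsoid semi-axes `c(z, y, x)` in mm.
#' @param csf_rim_mm Width of the peripheral CSF rim in mm.
#' @param hematoma_center_mm Hematoma centre offset from the brain centre,
#'   `c(z, y, x)` in mm.
#' @param hematoma_semiaxes_mm Hematoma ellipsoid semi-axes in mm.
#' @param edema_width_mm Width of the perihematomal edema shell in mm
#'   (default 6).
#' @param seed RNG seed controlling the noise draw.
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(grid = c(16L, 96L, 96L),
                           spacing = c(6, 0.5, 0.5),
                           hu = c(air = -1000, csf = 8, edema = 14,
                                  parenchyma = 30, hematoma = 70),
                           noise_sd = 4,
                           blur_sd = 0.6,
                           brain_semiaxes_mm = c(42, 22, 22),
                           csf_rim_mm = 2.5,
                           hematoma_center_mm = c(0, 0, 0),
                           hematoma_semiaxes_mm = c(15, 10, 10),
                           edema_width_mm = 6,
                           seed = 1L) {
  need <- c("air", "csf", "edema", "parenchyma", "hematoma")
  if (!all(need %in% names(hu))) {
    abort_invalid_config(paste("hu must name:", paste(need, collapse = ", ")))
  }
  if (!(hu[["edema"]] < hu[["parenchyma"]] && hu[["parenchyma"]] < hu[["hematoma"]])) {
    abort_invalid_config("tissue means must be ordered edema < parenchyma < hematoma")
  }
  if (noise_sd < 0) abort_invalid_config("noise_sd must be >= 0")
  if (blur_sd < 0) abort_invalid_config("blur_sd must be >= 0")
  if (length(grid) != 3L || any(grid < 2)) abort_invalid_config("grid must be 3 sizes >= 2")
  if (length(spacing) != 3L || any(spacing <= 0)) abort_invalid_config("spacing must be positive")
  if (any(brain_semiaxes_mm <= 0) || any(hematoma_semiaxes_mm <= 0)) {
    abort_invalid_config("semi-axes must be positive")
  }
  if (edema_width_mm < 0 || csf_rim_mm < 0) abort_invalid_config("widths must be >= 0")
  structure(
    list(grid = as.integer(grid), spacing = as.numeric(spacing), hu = hu,
         noise_sd = noise_sd, blur_sd = blur_sd,
         brain_semiaxes_mm = as.numeric(brain_semiaxes_mm),
         csf_rim_mm = csf_rim_mm,
         hematoma_center_mm = as.numeric(hematoma_center_mm),
         hematoma_semiaxes_mm = as.numeric(hematoma_semiaxes_mm),
         edema_width_mm = edema_width_mm, seed = as.integer(seed)),
    class = "phantom_config"
  )
}

# Voxel-centre coordinates (mm) along each axis, centred on the grid.
grid_axes_mm <- function(grid, spacing) {
  lapply(1:3, function(k) (seq_len(grid[k]) - (grid[k] + 1) / 2) * spacing[k])
}

#' Voxelize an ellipsoid on a phantom grid
#'
#' @param grid,spacing Grid size and spacing as in [phantom_config()].
#' @param center_mm Ellipsoid centre (z, y, x) in mm relative to grid centre.
#' @param semiaxes_mm Semi-axes (z, y, x) in mm.
#' @return Logical 3D array: voxel centres inside the ellipsoid.
#' @export
ellipsoid_mask <- function(grid, spacing, center_mm, semiaxes_mm) {
  ax <- grid_axes_mm(grid, spacing)
  qz <- ((ax[[1]] - center_mm[1]) / semiaxes_mm[1])^2
  qy <- ((ax[[2]] - center_mm[2]) / semiaxes_mm[2])^2
  qx <- ((ax[[3]] - center_mm[3]) / semiaxes_mm[3])^2
  outer(outer(qz, qy, "+"), qx, "+") <= 1
}

ellipsoid_volume_mL <- function(semiaxes_mm) 4 / 3 * pi * prod(semiaxes_mm) / 1000

# Pre-noise geometry: truth masks for one phantom case.
phantom_truth_masks <- function(config) {
  g <- config$grid; sp <- config$spacing
  brain <- ellipsoid_mask(g, sp, c(0, 0, 0), config$brain_semiaxes_mm)
  inner_semi <- pmax(config$brain_semiaxes_mm - config$csf_rim_mm, 1e-6)
  inner <- ellipsoid_mask(g, sp, c(0, 0, 0), inner_semi)
  hem <- ellipsoid_mask(g, sp, config$hematoma_center_mm, config$hematoma_semiaxes_mm)
  if (any(hem & !brain)) abort_invalid_config("hematoma ellipsoid extends outside the brain")
  if (!any(hem)) abort_invalid_config("hematoma ellipsoid contains no voxel centres")
  shell <- ellipsoid_mask(g, sp, config$hematoma_center_mm,
                          config$hematoma_semiaxes_mm + config$edema_width_mm)
  edema <- shell & inner & !hem
  list(brain = brain, csf = brain & !inner, hematoma = hem, edema = edema)
}

#' Generate a synthetic CT phantom case
#'
#' @param config A [phantom_config()].
#' @return Object of class `phantom_case`: `volume` (a [ct_volume()]),
#'   truth masks `truth_brain`, `truth_hematoma`, `truth_edema`, and
#'   `truth_volumes` (voxelized and analytic mL), plus the config and seed.
#'   Regeneration with the same config (and seed) is bit-identical.
#' @examples
#' p <- generate_phantom(phantom_config(noise_sd = 0, blur_sd = 0))
#' sort(unique(as.vector(p$volume$voxels)))  # exactly the five tissue HU
#' @export
generate_phantom <- function(config = phantom_config()) {
  if (!inherits(config, "phantom_config")) abort_invalid("config must be a phantom_config")
  tm <- phantom_truth_masks(config)
  hu <- config$hu
  img <- array(hu[["air"]], config$grid)
  img[tm$brain] <- hu[["parenchyma"]]
  img[tm$csf] <- hu[["csf"]]
  img[tm$edema] <- hu[["edema"]]
  img[tm$hematoma] <- hu[["hematoma"]]
  if (config$blur_sd > 0) img <- blur_inplane(img, config$blur_sd)
  if (config$noise_sd > 0) {
    img <- img + withr::with_seed(
      config$seed,
      array(stats::rnorm(prod(config$grid), 0, config$noise_sd), config$grid)
    )
  }
  vol_mm3 <- prod(config$spacing)
  structure(
    list(
      volume = ct_volume(img, config$spacing),
      truth_brain = tm$brain, truth_hematoma = tm$hematoma, truth_edema = tm$edema,
      truth_volumes = list(
        hematoma_mL = sum(tm$hematoma) * vol_mm3 / 1000,
        edema_mL = sum(tm$edema) * vol_mm3 / 1000,
        brain_mL = sum(tm$brain) * vol_mm3 / 1000,
        hematoma_analytic_mL = ellipsoid_volume_mL(config$hematoma_semiaxes_mm),
        edema_analytic_mL = ellipsoid_volume_mL(config$hematoma_semiaxes_mm +
                                                  config$edema_width_mm) -
          ellipsoid_volume_mL(config$hematoma_semiaxes_mm)
      ),
      config = config, seed = config$seed
    ),
    class = "phantom_case"
  )
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("Phantom case (seed %d): ", x$seed))
  print(x$volume)
  cat(sprintf("truth: hematoma %.2f mL, edema %.2f mL, brain %.1f mL\n",
              x$truth_volumes$hematoma_mL, x$truth_volumes$edema_mL,
              x$truth_volumes$brain_mL))
  invisible(x)
}

#' Generate a baseline / follow-up phantom pair
#'
#' Models the two-scan ICH protocol (initial CT within 6 h, re-examination
#' at 24 h). The follow-up hematoma semi-axes are scaled by
#' `growth_factor^(1/3)` so its *volume* scales by `growth_factor`; the edema
#' shell is re-derived around the grown hematoma. The truth enlargement
#' label is [classify_enlargement()] applied to the voxelized truth volumes.
#'
#' @param config Baseline [phantom_config()].
#' @param growth_factor Follow-up / baseline hematoma volume ratio (> 0).
#' @param seed Seed for the pair; baseline and follow-up noise draws are
#'   derived from it deterministically.
#' @return Object of class `phantom_pair`: `baseline`, `followup`,
#'   `growth_factor`, `truth_enlargement`.
#' @export
generate_longitudinal_pair <- function(config = phantom_config(), growth_factor = 1,
                                       seed = config$seed) {
  if (!is.finite(growth_factor) || growth_factor <= 0) {
    abort_invalid("growth_factor must be > 0")
  }
  base_cfg <- config
  base_cfg$seed <- as.integer(seed)
  fu_cfg <- config
  fu_cfg$hematoma_semiaxes_mm <- config$hematoma_semiaxes_mm * growth_factor^(1 / 3)
  fu_cfg$seed <- as.integer(seed + 499979L)  # independent follow-up noise
  baseline <- generate_phantom(base_cfg)
  followup <- generate_phantom(fu_cfg)
  structure(
    list(baseline = baseline, followup = followup, growth_factor = growth_factor,
         truth_enlargement = classify_enlargement(
           baseline$truth_volumes$hematoma_mL, followup$truth_volumes$hematoma_mL)),
    class = "phantom_pair"
  )
}

#' Cohort specification
#'
#' Defaults mirror a 150-patient early-ICH cohort split into 48 cases with
#' hematoma enlargement (observation group) and 102 without (control group).
#' Growth factors are drawn uniformly from `growth_enlarger` for enlargers
#' and `growth_stable` for the rest; the ranges are chosen with a safety
#' margin around the 33% relative threshold so that voxelization error
#' cannot flip a truth label. Baseline hematoma size varies per case via a
#' uniform scale on the semi-axes.
#'
#' @param n_cases Total cases (default 150).
#' @param n_enlargers Cases with true enlargement (default 48).
#' @param growth_enlarger,growth_stable Uniform ranges of the hematoma
#'   volume growth factor for each group.
#' @param size_scale Uniform range of the per-case baseline semi-axis scale.
#' @param covariate_preset `"ich-typical"` (group differences in blood
#'   pressure, ALC, NLR, HGB and the blend/low-density/island signs) or
#'   `"null"` (no group differences; for calibration studies).
#' @param seed Master seed for the cohort.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases = 150L, n_enlargers = 48L,
                        growth_enlarger = c(1.45, 2.2),
                        growth_stable = c(0.85, 1.18),
                        size_scale = c(0.8, 1.3),
                        covariate_preset = c("ich-typical", "null"),
                        seed = 1L) {
  covariate_preset <- match.arg(covariate_preset)
  if (n_enlargers > n_cases || n_cases < 2L || n_enlargers < 0L) {
    abort_invalid_config("need 0 <= n_enlargers <= n_cases and n_cases >= 2")
  }
  if (growth_enlarger[1] <= 1 + 0.33) {
    # leave headroom over the relative threshold; voxelization error is < 5%
    abort_invalid_config("growth_enlarger range must sit strictly above 1.33")
  }
  if (growth_stable[2] >= 1.33) {
    abort_invalid_config("growth_stable range must sit strictly below 1.33")
  }
  structure(
    list(n_cases = as.integer(n_cases), n_enlargers = as.integer(n_enlargers),
         growth_enlarger = growth_enlarger, growth_stable = growth_stable,
         size_scale = size_scale, covariate_preset = covariate_preset,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Group-specific covariate distributions. Continuous: (observation mean,
# control mean, common SD); binary signs: (observation incidence, control
# incidence). ALC/NLR/HGB levels echo reported serology for expansion vs
# non-expansion groups; their nominal unit is 10^9/L as reported, even
# though that unit is dimensionally odd for NLR (a ratio) and unusual for
# HGB -- the values are used verbatim as generator presets, not endorsed.
covariate_presets <- function(preset) {
  cont <- list(
    age = c(58.62, 58.62, 10.27),
    SBP = c(172, 158, 15), DBP = c(98, 90, 10),
    LDL = c(2.8, 2.8, 0.8), HDL = c(1.2, 1.2, 0.3),
    TC = c(4.6, 4.6, 1.0), TG = c(1.5, 1.5, 0.7),
    WBC = c(8.5, 8.5, 2.0), HGB = c(6.29, 4.25, 1.2),
    RBC = c(4.5, 4.5, 0.5), ANC = c(6.0, 6.0, 1.5),
    ALC = c(6.23, 6.08, 0.30), NLR = c(0.99, 1.43, 0.35)
  )
  signs <- list(
    male = c(0.46, 0.46),
    blend_sign = c(0.45, 0.15), low_density_sign = c(0.50, 0.20),
    island_sign = c(0.40, 0.12), satellite_sign = c(0.25, 0.25)
  )
  if (preset == "null") {
    cont <- lapply(cont, function(v) c(v[2], v[2], v[3]))
    signs <- lapply(signs, function(p) c(p[2], p[2]))
  }
  list(continuous = cont, signs = signs)
}

#' Simulate a cohort covariate table
#'
#' Draws the serological / blood-pressure / CT-sign covariates for an
#' observation (enlargement) vs control cohort. MAP is computed as
#' `(SBP + 2 DBP) / 3`.
#'
#' @param n_obs,n_ctrl Group sizes.
#' @param preset `"ich-typical"` or `"null"` (see [cohort_spec()]).
#' @param seed RNG seed.
#' @return `data.frame` with a `group` factor (`observation` / `control`),
#'   continuous columns and 0/1 sign columns.
#' @export
simulate_covariates <- function(n_obs = 48L, n_ctrl = 102L,
                                preset = c("ich-typical", "null"), seed = 1L) {
  preset <- match.arg(preset)
  pr <- covariate_presets(preset)
  n <- n_obs + n_ctrl
  obs <- c(rep(TRUE, n_obs), rep(FALSE, n_ctrl))
  withr::with_seed(seed, {
    df <- data.frame(group = factor(ifelse(obs, "observation", "control"),
                                    levels = c("observation", "control")))
    for (nm in names(pr$continuous)) {
      v <- pr$continuous[[nm]]
      df[[nm]] <- stats::rnorm(n, mean = ifelse(obs, v[1], v[2]), sd = v[3])
    }
    df$MAP <- (df$SBP + 2 * df$DBP) / 3
    for (nm in names(pr$signs)) {
      p <- pr$signs[[nm]]
      df[[nm]] <- stats::rbinom(n, 1L, ifelse(obs, p[1], p[2]))
    }
    df
  })
}

#' Generate a synthetic ICH cohort with ground truth
#'
#' Produces the case table of a two-scan cohort: per-case geometry scale,
#' growth factor, noise seed, voxelized truth volumes at both timepoints,
#' the truth enlargement label, and the covariate columns. Exactly
#' `n_enlargers` cases carry a true enlargement label, and every label is
#' consistent with [classify_enlargement()] re-applied to the truth volumes
#' (validated; violation is an error). Case order is randomised.
#'
#' Imaging pairs are *not* materialised here (150 volume pairs are bulky);
#' use [cohort_case_pair()] to regenerate any case's baseline/follow-up
#' phantoms bit-reproducibly from its row, or pass `dir` to write NIfTI
#' volumes, truth masks and the manifest/covariate CSVs to disk.
#'
#' @param spec A [cohort_spec()].
#' @param base_config Baseline [phantom_config()] shared by all cases.
#' @param dir Optional output directory for NIfTI + CSV export.
#' @return `data.frame` (class `cohort_table`) with one row per case.
#' @export
generate_cohort <- function(spec = cohort_spec(), base_config = phantom_config(),
                            dir = NULL) {
  if (!inherits(spec, "cohort_spec")) abort_invalid("spec must be a cohort_spec")
  n <- spec$n_cases
  k <- spec$n_enlargers
  tab <- withr::with_seed(spec$seed, {
    enlarger <- sample(c(rep(TRUE, k), rep(FALSE, n - k)))
    growth <- ifelse(enlarger,
                     stats::runif(n, spec$growth_enlarger[1], spec$growth_enlarger[2]),
                     stats::runif(n, spec$growth_stable[1], spec$growth_stable[2]))
    data.frame(
      case_id = sprintf("case_%03d", seq_len(n)),
      enlarger = enlarger,
      growth_factor = growth,
      size_scale = stats::runif(n, spec$size_scale[1], spec$size_scale[2]),
      noise_seed = sample.int(.Machine$integer.max %/% 2L, n)
    )
  })
  base_mL <- fu_mL <- numeric(n)
  truth <- logical(n)
  vol_mm3 <- prod(base_config$spacing)
  for (i in seq_len(n)) {
    cfg_b <- case_config(base_config, tab$size_scale[i], 1)
    cfg_f <- case_config(base_config, tab$size_scale[i], tab$growth_factor[i])
    base_mL[i] <- sum(phantom_truth_masks(cfg_b)$hematoma) * vol_mm3 / 1000
    fu_mL[i] <- sum(phantom_truth_masks(cfg_f)$hematoma) * vol_mm3 / 1000
    truth[i] <- classify_enlargement(base_mL[i], fu_mL[i])
  }
  if (!identical(truth, tab$enlarger)) {
    abort_invalid_config(
      "growth distributions are infeasible: truth labels contradict the enlargement thresholds")
  }
  tab$baseline_truth_mL <- base_mL
  tab$followup_truth_mL <- fu_mL
  tab$truth_enlargement <- truth
  tab$group <- factor(ifelse(truth, "observation", "control"),
                      levels = c("observation", "control"))
  cov <- simulate_covariates(
    n_obs = k, n_ctrl = n - k,
    preset = if (spec$covariate_preset == "null") "null" else "ich-typical",
    seed = spec$seed + 77003L
  )
  # covariates are drawn per group (observation rows first); align them to
  # the shuffled case order
  idx <- integer(n)
  idx[tab$enlarger] <- seq_len(k)
  idx[!tab$enlarger] <- k + seq_len(n - k)
  cov_all <- cov[idx, -1L, drop = FALSE]
  rownames(cov_all) <- NULL
  tab <- cbind(tab, cov_all)
  class(tab) <- c("cohort_table", "data.frame")
  attr(tab, "spec") <- spec
  attr(tab, "base_config") <- base_config
  if (!is.null(dir)) export_cohort(tab, dir)
  tab
}

case_config <- function(base_config, size_scale, growth_factor) {
  cfg <- base_config
  cfg$hematoma_semiaxes_mm <- base_config$hematoma_semiaxes_mm * size_scale *
    growth_factor^(1 / 3)
  cfg
}

#' Regenerate the phantom pair of one cohort case
#'
#' @param cohort A `cohort_table` from [generate_cohort()].
#' @param i Case row index.
#' @return A `phantom_pair` (see [generate_longitudinal_pair()]).
#' @export
cohort_case_pair <- function(cohort, i) {
  if (!inherits(cohort, "cohort_table")) abort_invalid("cohort must be a cohort_table")
  base_config <- attr(cohort, "base_config")
  cfg <- case_config(base_config, cohort$size_scale[i], 1)
  generate_longitudinal_pair(cfg, growth_factor = cohort$growth_factor[i],
                             seed = cohort$noise_seed[i])
}

export_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- as.data.frame(cohort)[, c("case_id", "enlarger", "growth_factor",
                                        "size_scale", "noise_seed",
                                        "baseline_truth_mL", "followup_truth_mL",
                                        "truth_enlargement")]
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  covcols <- setdiff(names(cohort), setdiff(names(manifest), "case_id"))
  utils::write.csv(as.data.frame(cohort)[, covcols],
                   file.path(dir, "covariates.csv"), row.names = FALSE)
  for (i in seq_len(nrow(cohort))) {
    pair <- cohort_case_pair(cohort, i)
    stem <- file.path(dir, cohort$case_id[i])
    write_ct_nifti(pair$baseline$volume, paste0(stem, "_baseline.nii.gz"))
    write_ct_nifti(pair$followup$volume, paste0(stem, "_followup.nii.gz"))
    write_ct_nifti(pair$baseline$truth_hematoma, paste0(stem, "_baseline_hematoma.nii.gz"),
                   spacing = pair$baseline$volume$spacing)
    write_ct_nifti(pair$followup$truth_hematoma, paste0(stem, "_followup_hematoma.nii.gz"),
                   spacing = pair$followup$volume$spacing)
  }
  invisible(dir)
}
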
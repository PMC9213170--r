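# CT-specific segmentation pipeline: intensity windowing, brain extraction,
# voxelwise FCM clustering, and hematoma / perihematomal-edema mask
# extraction from the defuzzified label map.
#
# Tissue classes are named by ascending fitted centre intensity. On
# non-contrast head CT the ordering is physical: CSF (~0-15 HU) <
# perihematomal edema (~10-20 HU) < normal parenchyma (~25-40 HU) <
# acute hematoma (~50-90 HU), so with the default Q = 4 the highest-centre
# cluster is the hematoma candidate and the second-lowest the edema
# candidate.

tissue_names_for <- function(Q) {
  if (Q == 4L) return(c("csf_low", "edema_candidate", "parenchyma", "hematoma"))
  nm <- sprintf("class_%02d", seq_len(Q))
  nm[Q] <- "hematoma"
  if (Q >= 2L) nm[2L] <- "edema_candidate"
  nm
}

#' Window CT intensities
#'
#' Clips intensities to a display/analysis window; the default 0-100 HU brain
#' window removes air and bone extremes before clustering so the fitted
#' centres describe soft-tissue contrast only.
#'
#' @param volume A [ct_volume()].
#' @param window_lo,window_hi Window bounds in HU (`window_lo < window_hi`).
#' @return A windowed [ct_volume()] on the same grid.
#' @export
ct_preprocess <- function(volume, window_lo = 0, window_hi = 100) {
  if (!is_ct_volume(volume)) abort_invalid("volume must be a ct_volume")
  if (window_lo >= window_hi) abort_invalid("window_lo must be < window_hi")
  ct_volume(pmin(pmax(volume$voxels, window_lo), window_hi), volume$spacing)
}

#' Extract a brain mask by thresholding
#'
#' Keeps voxels above the air threshold and below the bone threshold
#' (both applied to the *unwindowed* volume), retains the largest
#' 26-connected 3D component and fills in-plane holes. This is a phantom- and
#' pre-stripped-scan-grade extractor, not a radiology-grade skull stripper.
#'
#' @param volume A [ct_volume()] in original (unwindowed) HU.
#' @param air_thresh Lower HU bound for tissue (default -200).
#' @param bone_thresh Upper HU bound excluding bone (default 200).
#' @return Logical 3D array with spacing attached as attribute `"spacing"`.
#' @export
extract_brain_mask <- function(volume, air_thresh = -200, bone_thresh = 200) {
  if (!is_ct_volume(volume)) abort_invalid("volume must be a ct_volume")
  tissue <- volume$voxels > air_thresh & volume$voxels < bone_thresh
  if (!any(tissue)) abort_no_brain()
  m <- fill_holes_slicewise(largest_component(tissue, connectivity = 26))
  attr(m, "spacing") <- volume$spacing
  m
}

#' Segment a CT volume with fuzzy C-means
#'
#' Flattens in-mask voxel intensities into a one-feature sample set, fits
#' FCM ([fit_fcm()]), defuzzifies to the maximum-membership cluster, and
#' writes labels back at their voxel positions. Cluster indices are
#' relabelled by ascending fitted centre intensity so that label `Q-1` is
#' always the most hyperdense (hematoma-candidate) class; `tissue_order`
#' names the classes in that order.
#'
#' @param volume A (typically windowed) [ct_volume()].
#' @param mask Logical brain mask congruent with `volume`.
#' @param config An [fcm_config()]; default Q = 4, n = 2.
#' @param per_slice If TRUE, fit an independent FCM per axial slice instead
#'   of pooling the 3D intensity set (FCM uses no spatial context, so this
#'   only changes the intensity pool each fit sees).
#' @return An object of class `ct_labelmap`: `labels` (integer array, in-mask
#'   voxels 0..Q-1 by ascending centre, background -1), `tissue_order`,
#'   `centers` (sorted), `spacing`, and the underlying `fcm_fit` (pooled mode).
#' @export
segment_volume <- function(volume, mask, config = fcm_config(), per_slice = FALSE) {
  if (!is_ct_volume(volume)) abort_invalid("volume must be a ct_volume")
  mask <- as_mask(mask)
  if (!identical(dim(mask), dim(volume$voxels))) abort_invalid("mask and volume shapes differ")
  if (!any(mask)) abort_invalid("mask is empty")
  labels <- array(-1L, dim(mask))
  if (per_slice) {
    fits <- list()
    centers_acc <- 0
    nz <- dim(mask)[1L]
    used <- 0L
    for (z in seq_len(nz)) {
      mz <- mask[z, , ]
      if (!any(mz)) next
      vals <- volume$voxels[z, , ][mz]
      sl <- segment_samples(vals, config)
      lz <- labels[z, , ]
      lz[mz] <- sl$labels
      labels[z, , ] <- lz
      fits[[length(fits) + 1L]] <- sl$fit
      centers_acc <- centers_acc + sl$centers
      used <- used + 1L
    }
    centers <- centers_acc / used
    fit <- fits
  } else {
    seg <- segment_samples(volume$voxels[mask], config)
    labels[mask] <- seg$labels
    centers <- seg$centers
    fit <- seg$fit
  }
  structure(
    list(labels = labels, tissue_order = tissue_names_for(config$Q),
         centers = centers, spacing = volume$spacing, fcm = fit,
         config = config),
    class = "ct_labelmap"
  )
}

# Fit FCM on a 1D intensity vector and return 0-based labels relabelled by
# ascending centre intensity.
segment_samples <- function(vals, config) {
  if (length(unique(vals)) < config$Q) {
    abort_degenerate_input(sprintf(
      "fewer distinct intensities (%d) than clusters (Q = %d)",
      length(unique(vals)), config$Q))
  }
  fit <- fit_fcm(matrix(vals, ncol = 1L), config)
  ord <- order(fit$centers[, 1L])
  rank_of <- integer(config$Q)
  rank_of[ord] <- seq_len(config$Q)
  raw <- defuzzify(fit$memberships)        # 0-based, arbitrary cluster order
  list(labels = rank_of[raw + 1L] - 1L,    # 0-based, ascending-centre order
       centers = matrix(sort(fit$centers[, 1L]), ncol = 1L),
       fit = fit)
}

#' @export
print.ct_labelmap <- function(x, ...) {
  Q <- length(x$tissue_order)
  cat(sprintf("CT label map: Q = %d tissue classes (ascending HU):\n", Q))
  for (s in seq_len(Q)) {
    cat(sprintf("  %d: %-16s centre %.2f HU, %d voxels\n", s - 1L,
                x$tissue_order[s], x$centers[s, 1L], sum(x$labels == s - 1L)))
  }
  cat(sprintf("  background (-1): %d voxels\n", sum(x$labels == -1L)))
  invisible(x)
}

tissue_class_index <- function(labelmap, tissue) {
  i <- match(tissue, labelmap$tissue_order)
  if (is.na(i)) abort_invalid(sprintf("no tissue class named '%s'", tissue))
  i - 1L
}

new_tissue_mask <- function(mask, role, spacing, empty_flag = FALSE) {
  attr(mask, "role") <- role
  attr(mask, "spacing") <- spacing
  attr(mask, "empty") <- empty_flag
  mask
}

#' Extract the hematoma mask from a label map
#'
#' Takes the voxels of the highest-intensity (hematoma-candidate) class,
#' removes connected components smaller than `min_size_voxels`
#' (26-connectivity), and keeps the single largest remaining component as
#' the hematoma. An absent hematoma class is not an error -- the returned
#' all-FALSE mask carries attribute `empty = TRUE` (a patient may simply have
#' no visible bleed).
#'
#' @param labelmap A `ct_labelmap` from [segment_volume()].
#' @param min_size_voxels Minimum component size retained (default 50).
#' @param connectivity Passed to [label_components()] (default 26).
#' @return Logical 3D array with attributes `role = "hematoma"`, `spacing`,
#'   and `empty`.
#' @export
extract_hematoma_mask <- function(labelmap, min_size_voxels = 50, connectivity = 26) {
  if (!inherits(labelmap, "ct_labelmap")) abort_invalid("labelmap must be a ct_labelmap")
  cls <- length(labelmap$tissue_order) - 1L
  sel <- labelmap$labels == cls
  if (!any(sel)) {
    return(new_tissue_mask(array(FALSE, dim(labelmap$labels)), "hematoma",
                           labelmap$spacing, empty_flag = TRUE))
  }
  cc <- label_components(sel, connectivity)
  keep <- which(cc$sizes >= min_size_voxels)
  if (length(keep) == 0L) {
    return(new_tissue_mask(array(FALSE, dim(labelmap$labels)), "hematoma",
                           labelmap$spacing, empty_flag = TRUE))
  }
  new_tissue_mask(cc$labels == 1L, "hematoma", labelmap$spacing)
}

#' Extract the perihematomal edema mask
#'
#' Perihematomal edema is hypodense fluid surrounding the bleed; no closed
#' extraction rule is standard, so a dilation-ring heuristic is used: voxels
#' of the designated hypodense (edema-candidate) class that lie within a
#' morphological dilation of the hematoma by `ring_mm` (anisotropy-aware),
#' hematoma voxels excluded. An empty hematoma yields an empty edema mask.
#'
#' @param labelmap A `ct_labelmap`.
#' @param hematoma Hematoma mask from [extract_hematoma_mask()].
#' @param ring_mm Ring radius in mm (default 10).
#' @param edema_class Tissue-class name to harvest (default
#'   `"edema_candidate"`, the second-lowest centre).
#' @return Logical 3D array with attributes `role = "edema"`, `spacing`,
#'   `empty`.
#' @export
extract_edema_mask <- function(labelmap, hematoma, ring_mm = 10,
                               edema_class = "edema_candidate") {
  if (!inherits(labelmap, "ct_labelmap")) abort_invalid("labelmap must be a ct_labelmap")
  hematoma <- as_mask(hematoma)
  if (!identical(dim(hematoma), dim(labelmap$labels))) {
    abort_invalid("hematoma mask and label map shapes differ")
  }
  if (!any(hematoma)) {
    return(new_tissue_mask(array(FALSE, dim(labelmap$labels)), "edema",
                           labelmap$spacing, empty_flag = TRUE))
  }
  cls <- tissue_class_index(labelmap, edema_class)
  ring <- dilate_mm(hematoma, labelmap$spacing, ring_mm)
  m <- (labelmap$labels == cls) & ring & !hematoma
  new_tissue_mask(m, "edema", labelmap$spacing, empty_flag = !any(m))
}

#' Run the full hematoma segmentation pipeline
#'
#' Convenience wrapper: brain extraction on the raw volume, windowing, FCM
#' segmentation, hematoma and edema mask extraction.
#'
#' @param volume A raw [ct_volume()] in HU.
#' @param config An [fcm_config()].
#' @param window_lo,window_hi Brain window passed to [ct_preprocess()].
#' @param min_size_voxels,ring_mm Post-processing parameters.
#' @return List with `brain_mask`, `labelmap`, `hematoma`, `edema`.
#' @export
segment_ich <- function(volume, config = fcm_config(), window_lo = 0,
                        window_hi = 100, min_size_voxels = 50, ring_mm = 10) {
  brain <- extract_brain_mask(volume)
  win <- ct_preprocess(volume, window_lo, window_hi)
  lm <- segment_volume(win, brain, config)
  hem <- extract_hematoma_mask(lm, min_size_voxels = min_size_voxels)
  ede <- extract_edema_mask(lm, hem, ring_mm = ring_mm)
  list(brain_mask = brain, labelmap = lm, hematoma = hem, edema = ede)
}
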
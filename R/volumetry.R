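# Physical volumetry and the two-timepoint hematoma-enlargement criterion.
#
# ICH protocols image twice: an initial scan within 6 h of onset and a
# re-examination at 24 h. Hematoma enlargement (expansion) is the widely
# used composite criterion: absolute growth of at least 12.5 mL, or relative
# growth over 33%, between the two scans.

#' Physical volume of a binary mask
#'
#' @param mask Logical 3D array.
#' @param spacing Voxel spacing `c(dz, dy, dx)` in mm; taken from the mask's
#'   `"spacing"` attribute when present.
#' @return Volume in mL (`voxels * dz*dy*dx / 1000`).
#' @examples
#' m <- array(TRUE, c(10, 10, 10))
#' mask_volume_mL(m, spacing = c(6, 0.5, 0.5))
#' @export
mask_volume_mL <- function(mask, spacing = attr(mask, "spacing")) {
  mask <- as_mask(mask)
  if (is.null(spacing)) abort_invalid("spacing is required (none attached to mask)")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort_invalid("spacing must be 3 strictly positive values")
  }
  sum(mask) * prod(spacing) / 1000
}

#' Relative edema volume
#'
#' Ratio of perihematomal edema volume to hematoma volume at a single
#' timepoint. Undefined (returned as `NA`) when the hematoma volume is zero.
#'
#' @param edema_mL,hematoma_mL Non-negative volumes in mL.
#' @return `edema_mL / hematoma_mL`, or `NA_real_` when undefined.
#' @export
relative_edema_volume <- function(edema_mL, hematoma_mL) {
  if (!is.finite(edema_mL) || !is.finite(hematoma_mL) ||
      edema_mL < 0 || hematoma_mL < 0) {
    abort_invalid("volumes must be finite and >= 0")
  }
  if (hematoma_mL == 0) return(NA_real_)
  edema_mL / hematoma_mL
}

#' Volume report for one timepoint
#'
#' @param hematoma Hematoma mask (logical array).
#' @param edema Edema mask (logical array), optional.
#' @param spacing Voxel spacing in mm; defaults to the hematoma mask's
#'   attribute.
#' @return Object of class `volume_report`: `hematoma_mL`, `edema_mL`,
#'   `relative_edema` (`NA` when the hematoma is empty), `spacing`.
#' @export
volume_report <- function(hematoma, edema = NULL, spacing = attr(hematoma, "spacing")) {
  hem_mL <- mask_volume_mL(hematoma, spacing)
  ede_mL <- if (is.null(edema)) 0 else mask_volume_mL(edema, spacing)
  structure(
    list(hematoma_mL = hem_mL, edema_mL = ede_mL,
         relative_edema = relative_edema_volume(ede_mL, hem_mL),
         spacing = as.numeric(spacing)),
    class = "volume_report"
  )
}

#' @export
print.volume_report <- function(x, ...) {
  cat(sprintf("hematoma %.2f mL | edema %.2f mL | relative edema %s\n",
              x$hematoma_mL, x$edema_mL,
              if (is.na(x$relative_edema)) "undefined" else sprintf("%.3f", x$relative_edema)))
  invisible(x)
}

#' Classify hematoma enlargement between two scans
#'
#' TRUE when the follow-up hematoma has grown by at least `abs_thresh_mL`
#' (inclusive, "by 12.5 mL") or by strictly more than `rel_thresh`
#' relative to baseline ("over 33%").
#'
#' @param baseline_mL Baseline hematoma volume in mL (> 0).
#' @param followup_mL Follow-up hematoma volume in mL (>= 0).
#' @param abs_thresh_mL Absolute growth threshold, default 12.5 mL.
#' @param rel_thresh Relative growth threshold, default 0.33.
#' @return Logical.
#' @examples
#' classify_enlargement(20, 33)   # +13 mL        -> TRUE
#' classify_enlargement(10, 13)   # +3 mL, +30%   -> FALSE
#' classify_enlargement(6, 8.5)   # +41.7% > 33%  -> TRUE
#' @export
classify_enlargement <- function(baseline_mL, followup_mL,
                                 abs_thresh_mL = 12.5, rel_thresh = 0.33) {
  if (!is.finite(baseline_mL) || baseline_mL <= 0) {
    abort_invalid("baseline volume must be > 0")
  }
  if (!is.finite(followup_mL) || followup_mL < 0) {
    abort_invalid("follow-up volume must be >= 0")
  }
  delta <- followup_mL - baseline_mL
  (delta >= abs_thresh_mL) || (delta / baseline_mL > rel_thresh)
}

#' Compare baseline and follow-up volume reports
#'
#' @param baseline,followup [volume_report()]s for the initial (within 6 h)
#'   and re-examination (24 h) scans.
#' @param abs_thresh_mL,rel_thresh Enlargement thresholds, see
#'   [classify_enlargement()].
#' @param relative_edema_mode `"per_timepoint"` reports each scan's
#'   edema/hematoma ratio; `"cross_timepoint"` additionally reports the
#'   follow-up/baseline edema ratio.
#' @return Object of class `longitudinal_comparison` with hematoma and edema
#'   deltas, `percent_change`, and the `enlargement` verdict.
#' @export
compare_timepoints <- function(baseline, followup, abs_thresh_mL = 12.5,
                               rel_thresh = 0.33,
                               relative_edema_mode = c("per_timepoint", "cross_timepoint")) {
  relative_edema_mode <- match.arg(relative_edema_mode)
  for (r in list(baseline, followup)) {
    if (!inherits(r, "volume_report")) abort_invalid("both arguments must be volume_reports")
  }
  delta_h <- followup$hematoma_mL - baseline$hematoma_mL
  pct <- if (baseline$hematoma_mL > 0) delta_h / baseline$hematoma_mL else NA_real_
  out <- list(
    baseline = baseline, followup = followup,
    delta_hematoma_mL = delta_h,
    delta_edema_mL = followup$edema_mL - baseline$edema_mL,
    percent_change = pct,
    enlargement = classify_enlargement(baseline$hematoma_mL, followup$hematoma_mL,
                                       abs_thresh_mL, rel_thresh),
    relative_edema_baseline = baseline$relative_edema,
    relative_edema_followup = followup$relative_edema,
    relative_edema_mode = relative_edema_mode
  )
  if (relative_edema_mode == "cross_timepoint") {
    out$relative_edema_cross <- if (baseline$edema_mL > 0) {
      followup$edema_mL / baseline$edema_mL
    } else NA_real_
  }
  structure(out, class = "longitudinal_comparison")
}

#' @export
print.longitudinal_comparison <- function(x, ...) {
  cat(sprintf("hematoma: %.2f -> %.2f mL (delta %+.2f mL, %s)\n",
              x$baseline$hematoma_mL, x$followup$hematoma_mL, x$delta_hematoma_mL,
              if (is.na(x$percent_change)) "n/a" else sprintf("%+.1f%%", 100 * x$percent_change)))
  cat(sprintf("edema:    %.2f -> %.2f mL (delta %+.2f mL)\n",
              x$baseline$edema_mL, x$followup$edema_mL, x$delta_edema_mL))
  cat(sprintf("enlargement (>= 12.5 mL or > 33%%): %s\n",
              if (x$enlargement) "YES" else "no"))
  invisible(x)
}
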
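# Voxel-overlap quality metrics for truth/predicted mask pairs.
#
# Region semantics: within the evaluation domain (normally the brain mask),
#   a = truth-positive region, b = predicted-positive region,
#   c = truth-negative region, d = predicted-negative region.
# The metrics are the standard forms
#   sensitivity = |a n b| / |a|,  specificity = |c n d| / |c|,
#   dice        = 2 |a n b| / (|a| + |b|).
# (Intersections of the *disjoint* regions a/c or b/d are degenerate by
# construction; only the truth-vs-predicted intersections are informative.)
# Restricting to the brain mask matters: counting the full image grid as
# negatives inflates specificity with trivially empty background.

#' Tally a truth/predicted region pair
#'
#' @param truth Logical truth-positive mask.
#' @param predicted Logical predicted-positive mask, same shape.
#' @param domain Optional logical evaluation domain (e.g. brain mask); both
#'   masks must be subsets of it. `NULL` uses the whole grid.
#' @return Object of class `region_pair`: counts `a`, `b`, `ab`, `c`, `cd`
#'   and the domain size `n`.
#' @export
region_pair <- function(truth, predicted, domain = NULL) {
  truth <- as_metric_mask(truth)
  predicted <- as_metric_mask(predicted)
  if (!identical(dim(truth), dim(predicted))) abort_invalid("truth/predicted shapes differ")
  if (!is.null(domain)) {
    domain <- as_metric_mask(domain)
    if (!identical(dim(domain), dim(truth))) abort_invalid("domain shape differs")
    if (any(truth & !domain) || any(predicted & !domain)) {
      abort_invalid("masks must be subsets of the evaluation domain")
    }
    truth <- truth[domain]
    predicted <- predicted[domain]
  }
  structure(
    list(a = sum(truth), b = sum(predicted), ab = sum(truth & predicted),
         c = sum(!truth), cd = sum(!truth & !predicted), n = length(truth)),
    class = "region_pair"
  )
}

as_metric_mask <- function(x) {
  if (is.null(dim(x))) x <- array(x, length(x))
  storage.mode(x) <- "logical"
  if (anyNA(x)) abort_invalid("masks must not contain NA")
  x
}

as_region_pair <- function(pair) {
  if (!inherits(pair, "region_pair")) abort_invalid("expected a region_pair")
  pair
}

#' Segmentation sensitivity
#'
#' Fraction of truth-positive voxels recovered by the prediction,
#' `|a n b| / |a|`. `NaN` when the truth region is empty.
#'
#' @param pair A [region_pair()].
#' @return Number in `[0, 1]`, or `NaN` if undefined.
#' @export
seg_sensitivity <- function(pair) {
  pair <- as_region_pair(pair)
  if (pair$a == 0) return(NaN)
  pair$ab / pair$a
}

#' Segmentation specificity
#'
#' Fraction of truth-negative voxels predicted negative, `|c n d| / |c|`.
#' `NaN` when there are no truth negatives in the domain.
#'
#' @inheritParams seg_sensitivity
#' @return Number in `[0, 1]`, or `NaN` if undefined.
#' @export
seg_specificity <- function(pair) {
  pair <- as_region_pair(pair)
  if (pair$c == 0) return(NaN)
  pair$cd / pair$c
}

#' Dice overlap coefficient
#'
#' `2 |a n b| / (|a| + |b|)`. `NaN` when both masks are empty.
#'
#' @inheritParams seg_sensitivity
#' @return Number in `[0, 1]`, or `NaN` if undefined.
#' @export
seg_dice <- function(pair) {
  pair <- as_region_pair(pair)
  if (pair$a + pair$b == 0) return(NaN)
  2 * pair$ab / (pair$a + pair$b)
}

#' Evaluate a predicted mask against ground truth
#'
#' Assembles the [region_pair()] within the evaluation domain and computes
#' sensitivity, specificity and Dice plus the underlying voxel counts.
#' Undefined metrics are reported as `NaN` and listed in `undefined` rather
#' than raised as errors.
#'
#' @inheritParams region_pair
#' @return Object of class `metric_report`: `sensitivity`, `specificity`,
#'   `dice`, `counts` (the region pair), `undefined` (character vector).
#' @examples
#' truth <- array(FALSE, c(1, 10, 10)); truth[1, 3:5, 3:5] <- TRUE
#' evaluate_segmentation(truth, truth)
#' @export
evaluate_segmentation <- function(truth, predicted, domain = NULL) {
  pair <- region_pair(truth, predicted, domain)
  out <- list(
    sensitivity = seg_sensitivity(pair),
    specificity = seg_specificity(pair),
    dice = seg_dice(pair),
    counts = pair
  )
  out$undefined <- names(which(vapply(out[c("sensitivity", "specificity", "dice")],
                                      is.nan, logical(1))))
  structure(out, class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("sensitivity %.4f | specificity %.4f | dice %.4f\n",
              x$sensitivity, x$specificity, x$dice))
  cat(sprintf("counts: |a| = %d, |b| = %d, |a n b| = %d, |c n d| = %d (domain %d)\n",
              x$counts$a, x$counts$b, x$counts$ab, x$counts$cd, x$counts$n))
  if (length(x$undefined)) cat("undefined:", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' Flatten a metric report to a one-row data frame
#'
#' Useful for accumulating per-case CSV rows in cohort evaluations.
#'
#' @param x A `metric_report`.
#' @param case Optional case identifier column.
#' @return A one-row `data.frame`.
#' @export
metric_report_row <- function(x, case = NA_character_) {
  if (!inherits(x, "metric_report")) abort_invalid("x must be a metric_report")
  data.frame(case = case, sensitivity = x$sensitivity,
             specificity = x$specificity, dice = x$dice,
             truth_voxels = x$counts$a, predicted_voxels = x$counts$b,
             overlap_voxels = x$counts$ab, stringsAsFactors = FALSE)
}
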
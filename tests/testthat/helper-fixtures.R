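# Shared fixtures, built in code at test time.

# Compact phantom for property tests where the default 16x96x96 grid would be
# needlessly slow; same tissue contrast, scaled-down geometry.
small_phantom_config <- function(...) {
  phantom_config(
    grid = c(10L, 64L, 64L), spacing = c(6, 0.5, 0.5),
    brain_semiaxes_mm = c(27, 14, 14), csf_rim_mm = 2,
    hematoma_semiaxes_mm = c(10, 7, 7), edema_width_mm = 4,
    ...
  )
}

# Hand-buildable label map carrying the ct_labelmap contract.
make_toy_labelmap <- function(labels, Q = 4L, spacing = c(6, 0.5, 0.5)) {
  structure(
    list(labels = labels,
         tissue_order = fcmseg:::tissue_names_for(Q),
         centers = matrix(seq_len(Q) * 20, ncol = 1),
         spacing = spacing,
         fcm = NULL, config = fcm_config(Q = Q)),
    class = "ct_labelmap"
  )
}

# Independent confusion-matrix tally (the metric oracle): plain voxel loop
# over TP/FP/TN/FN, no reuse of the package's counting.
confusion_tally <- function(truth, predicted, domain = NULL) {
  t <- as.logical(truth); p <- as.logical(predicted)
  if (!is.null(domain)) {
    d <- as.logical(domain)
    t <- t[d]; p <- p[d]
  }
  tp <- sum(t & p); fn <- sum(t & !p); fp <- sum(!t & p); tn <- sum(!t & !p)
  list(sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       dice = 2 * tp / (2 * tp + fp + fn))
}

# Bayes-optimal accuracy of labelling a voxel mixture with known class means
# and Gaussian noise: per class, mass assigned correctly when the noisy value
# falls on the class's side of the midpoints to the neighbouring means.
bayes_accuracy <- function(class_counts, means, noise_sd) {
  ord <- order(means)
  means <- means[ord]; class_counts <- class_counts[ord]
  k <- length(means)
  cuts <- c(-Inf, (means[-k] + means[-1]) / 2, Inf)
  correct <- vapply(seq_len(k), function(i) {
    stats::pnorm(cuts[i + 1], means[i], noise_sd) -
      stats::pnorm(cuts[i], means[i], noise_sd)
  }, 1)
  sum(class_counts * correct) / sum(class_counts)
}

# Truth tissue-class labels (ascending-HU coding, -1 outside brain) for a
# phantom case, for voxelwise accuracy checks.
phantom_truth_labels <- function(case) {
  tm <- fcmseg:::phantom_truth_masks(case$config)
  lab <- array(-1L, dim(tm$brain))
  lab[tm$brain] <- 2L       # parenchyma
  lab[tm$csf] <- 0L
  lab[tm$edema] <- 1L
  lab[tm$hematoma] <- 3L
  lab
}
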
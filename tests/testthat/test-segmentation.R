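# CT segmentation pipeline against phantom ground truth.

test_that("windowing clips to the brain window and preserves geometry", {
  v <- ct_volume(array(c(-1000, 50, 2000, 30), c(1, 2, 2)), c(6, 0.5, 0.5))
  w <- ct_preprocess(v)
  expect_equal(sort(as.vector(w$voxels)), c(0, 30, 50, 100))
  inw <- ct_volume(array(runif(8, 10, 90), c(2, 2, 2)))
  expect_equal(ct_preprocess(inw)$voxels, inw$voxels)
  expect_equal(w$spacing, v$spacing)
  expect_error(ct_preprocess(v, 100, 0), class = "fcmseg_invalid_input")
})

test_that("brain extraction recovers the phantom brain and rejects air", {
  p <- generate_phantom(phantom_config(seed = 3))
  bm <- extract_brain_mask(p$volume)
  expect_gte(seg_dice(region_pair(p$truth_brain, bm)), 0.95)
  expect_true(all(p$volume$voxels[bm] > -200))
  air <- ct_volume(array(-1000, c(4, 10, 10)))
  expect_error(extract_brain_mask(air), class = "fcmseg_no_brain_found")
})

test_that("segmentation orders tissue classes by centre intensity and labels only the mask", {
  p <- generate_phantom(phantom_config(seed = 5))
  bm <- extract_brain_mask(p$volume)
  lm <- segment_volume(ct_preprocess(p$volume), bm)
  expect_identical(lm$tissue_order,
                   c("csf_low", "edema_candidate", "parenchyma", "hematoma"))
  expect_true(all(diff(lm$centers[, 1]) > 0))
  expect_true(all(lm$labels[!bm] == -1L))
  expect_true(all(lm$labels[bm] %in% 0:3))
  # the hematoma class sits on the hyperdense centre
  expect_gt(lm$centers[4, 1], 50)
})

test_that("voxel labelling approaches the Bayes accuracy of the intensity mixture", {
  # oracle: Gaussian-mixture Bayes accuracy given true class means/counts
  p <- generate_phantom(phantom_config(seed = 2))
  bm <- extract_brain_mask(p$volume)
  lm <- segment_volume(ct_preprocess(p$volume), bm)
  truth <- phantom_truth_labels(p)
  sel <- bm & truth >= 0L
  acc <- mean(lm$labels[sel] == truth[sel])
  hu <- p$config$hu[c("csf", "edema", "parenchyma", "hematoma")]
  counts <- vapply(0:3, function(k) sum(truth[sel] == k), 1L)
  ceiling_acc <- bayes_accuracy(counts, as.numeric(hu), p$config$noise_sd)
  expect_gte(acc, ceiling_acc - 0.05)
  # on a phantom whose four levels are separable at noise sd 4 the pipeline
  # recovers >= 90% of voxel labels
  cfg <- phantom_config(seed = 2, hu = c(air = -1000, csf = 0, edema = 15,
                                         parenchyma = 32, hematoma = 70))
  p2 <- generate_phantom(cfg)
  bm2 <- extract_brain_mask(p2$volume)
  lm2 <- segment_volume(ct_preprocess(p2$volume), bm2)
  truth2 <- phantom_truth_labels(p2)
  sel2 <- bm2 & truth2 >= 0L
  expect_gte(mean(lm2$labels[sel2] == truth2[sel2]), 0.9)
})

test_that("degenerate inputs raise classed errors", {
  flat <- ct_volume(array(30, c(2, 10, 10)))
  mask <- array(TRUE, c(2, 10, 10))
  expect_error(segment_volume(flat, mask), class = "fcmseg_degenerate_input")
  p <- generate_phantom(small_phantom_config())
  expect_error(segment_volume(ct_preprocess(p$volume), array(FALSE, dim(p$volume$voxels))),
               class = "fcmseg_invalid_input")
})

test_that("hematoma extraction keeps the largest component above the size floor", {
  labels <- array(-1L, c(4, 30, 30))
  labels[labels == -1L] <- 2L
  labels[2, 3:12, 3:12] <- 3L      # 100-voxel slab per slice pair: big blob
  labels[3, 3:7, 3:12] <- 3L
  labels[1, 25:29, 25:30 - 1] <- 3L  # 30-voxel blob
  lm <- make_toy_labelmap(labels)
  hm <- extract_hematoma_mask(lm, min_size_voxels = 50)
  expect_equal(sum(hm), 150)
  expect_false(any(hm[1, , ]))
  expect_false(attr(hm, "empty"))
  # no hematoma-class voxels: empty mask with the flag set, not an error
  lm0 <- make_toy_labelmap(array(1L, c(2, 5, 5)))
  hm0 <- extract_hematoma_mask(lm0)
  expect_false(any(hm0))
  expect_true(attr(hm0, "empty"))
})

test_that("phantom hematoma and edema masks meet their overlap floors at noise sd 4", {
  p <- generate_phantom(phantom_config(seed = 1))
  seg <- segment_ich(p$volume)
  hem <- evaluate_segmentation(p$truth_hematoma, seg$hematoma, seg$brain_mask)
  expect_gte(hem$dice, 0.90)
  cc <- label_components(seg$hematoma)
  expect_equal(cc$n, 1L)
  ede <- evaluate_segmentation(p$truth_edema, seg$edema, seg$brain_mask)
  expect_gte(ede$dice, 0.75)
})

test_that("masks nest inside the brain and hematoma excludes edema", {
  p <- generate_phantom(small_phantom_config(seed = 9))
  seg <- segment_ich(p$volume)
  expect_true(all(seg$brain_mask[seg$hematoma]))
  expect_true(all(seg$brain_mask[seg$edema]))
  expect_false(any(seg$hematoma & seg$edema))
})

test_that("an empty hematoma propagates to an empty edema mask", {
  lm <- make_toy_labelmap(array(1L, c(2, 6, 6)))
  hm <- extract_hematoma_mask(lm)
  em <- extract_edema_mask(lm, hm)
  expect_false(any(em))
  expect_true(attr(em, "empty"))
})

test_that("edema voxels stay within the dilation ring of the hematoma", {
  p <- generate_phantom(small_phantom_config(seed = 4))
  seg <- segment_ich(p$volume, ring_mm = 8)
  ring <- dilate_mm(seg$hematoma, p$volume$spacing, 8)
  expect_true(all(ring[seg$edema]))
})

test_that("segmentation is idempotent: same volume, config and seed, same labels", {
  p <- generate_phantom(small_phantom_config(seed = 6))
  bm <- extract_brain_mask(p$volume)
  w <- ct_preprocess(p$volume)
  lm1 <- segment_volume(w, bm)
  lm2 <- segment_volume(w, bm)
  expect_identical(lm1$labels, lm2$labels)
  expect_identical(lm1$centers, lm2$centers)
})

test_that("per-slice mode segments each slice independently but stays mask-confined", {
  p <- generate_phantom(small_phantom_config(seed = 8))
  bm <- extract_brain_mask(p$volume)
  lm <- segment_volume(ct_preprocess(p$volume), bm, fcm_config(Q = 3), per_slice = TRUE)
  expect_true(all(lm$labels[!bm] == -1L))
  expect_true(all(lm$labels[bm] %in% 0:2))
})
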
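# CT volume container. Arrays are indexed (z, y, x), 0-based slice first,
# with spacing c(dz, dy, dx) in mm; NIfTI files store (x, y, z), so I/O
# permutes axes. The default 6 mm slice thickness matches routine 16-slice
# non-contrast head CT acquisition (6 mm slices at 6 mm intervals).

#' Construct a CT volume
#'
#' @param voxels Numeric 3D array of intensities in Hounsfield units,
#'   indexed (slice z, row y, column x).
#' @param spacing Voxel spacing `c(dz, dy, dx)` in mm; defaults to 6 mm
#'   slices with 0.5 mm in-plane pixels.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing = c(6, 0.5, 0.5)) {
  if (length(dim(voxels)) != 3L) abort_invalid("voxels must be a 3D array (z, y, x)")
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0)) {
    abort_invalid("spacing must be 3 strictly positive values (dz, dy, dx) in mm")
  }
  if (!all(is.finite(voxels))) abort_invalid("voxel intensities must be finite")
  structure(list(voxels = voxels, spacing = as.numeric(spacing)), class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("CT volume: %d x %d x %d voxels (z, y, x), spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("intensity range: [%.1f, %.1f] HU\n", min(x$voxels), max(x$voxels)))
  invisible(x)
}

is_ct_volume <- function(x) inherits(x, "ct_volume")

#' Read a CT volume from NIfTI
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [ct_volume()] with the array permuted to (z, y, x) and spacing
#'   taken from the NIfTI pixdim.
#' @export
read_ct_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) abort_invalid("expected a 3D NIfTI volume")
  pd <- RNifti::pixdim(img)  # (dx, dy, dz)
  ct_volume(aperm(arr, c(3L, 2L, 1L)), spacing = rev(pd[seq_len(3L)]))
}

#' Write a CT volume (or mask) to NIfTI
#'
#' Masks are written as 0/1 integer volumes on the same grid.
#'
#' @param x A [ct_volume()], or a 3D array with `spacing` supplied.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param spacing Required when `x` is a bare array.
#' @return `path`, invisibly.
#' @export
write_ct_nifti <- function(x, path, spacing = NULL) {
  if (is_ct_volume(x)) {
    arr <- x$voxels
    spacing <- x$spacing
  } else {
    if (is.null(spacing)) abort_invalid("spacing is required when writing a bare array")
    arr <- x
  }
  if (is.logical(arr)) {
    arr <- array(as.integer(arr), dim(arr))
  }
  img <- RNifti::asNifti(aperm(arr, c(3L, 2L, 1L)))
  RNifti::pixdim(img) <- rev(as.numeric(spacing))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary mask from NIfTI
#'
#' @param path Path to a mask NIfTI (any nonzero voxel is TRUE).
#' @return Logical 3D array (z, y, x) with the spacing attached as
#'   attribute `"spacing"`.
#' @export
read_mask_nifti <- function(path) {
  vol <- read_ct_nifti(path)
  m <- vol$voxels != 0
  attr(m, "spacing") <- vol$spacing
  m
}

#' Import a per-slice PNG stack as a CT volume
#'
#' Reads 8-bit grayscale PNG slices (sorted by file name, caudal to cranial)
#' and rescales them to Hounsfield units via a JSON sidecar containing
#' `rescale_slope`, `rescale_intercept` and `spacing` `[dz, dy, dx]`:
#' `HU = slope * raw8 + intercept` with `raw8` in 0..255.
#'
#' @param dir Directory containing the PNG slices.
#' @param sidecar Path to the sidecar JSON (default `meta.json` inside `dir`).
#' @param pattern Regular expression selecting the slice files.
#' @return A [ct_volume()].
#' @export
read_ct_png_stack <- function(dir, sidecar = file.path(dir, "meta.json"),
                              pattern = "\\.png$") {
  if (!requireNamespace("png", quietly = TRUE)) {
    abort_invalid("the 'png' package is required to read PNG stacks")
  }
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  if (length(files) == 0L) abort_invalid(sprintf("no PNG slices found in %s", dir))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (f in c("rescale_slope", "rescale_intercept", "spacing")) {
    if (is.null(meta[[f]])) abort_invalid(sprintf("sidecar is missing '%s'", f))
  }
  slices <- lapply(files, function(f) {
    s <- png::readPNG(f)
    if (length(dim(s)) == 3L) s <- s[, , 1L]  # grayscale from RGB(A)
    round(s * 255)
  })
  d2 <- dim(slices[[1L]])
  vox <- array(NA_real_, c(length(slices), d2[1L], d2[2L]))
  for (z in seq_along(slices)) vox[z, , ] <- slices[[z]]
  vox <- meta$rescale_slope * vox + meta$rescale_intercept
  ct_volume(vox, spacing = as.numeric(meta$spacing))
}
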
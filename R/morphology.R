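# Binary-mask utilities shared by the segmentation and phantom code.
# Masks are logical 3D arrays indexed (z, y, x).

neighbour_offsets <- function(connectivity) {
  # Half of the neighbourhood (lexicographically positive offsets) is enough
  # for an undirected adjacency graph.
  grid <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  grid <- grid[order(grid$dz, grid$dy, grid$dx), ]
  keep <- switch(as.character(connectivity),
    "26" = rep(TRUE, nrow(grid)),
    "6"  = abs(grid$dz) + abs(grid$dy) + abs(grid$dx) == 1,
    "8"  = grid$dz == 0,  # per-slice 8-neighbourhood
    abort_invalid("connectivity must be 6, 8 or 26")
  )
  grid <- grid[keep & !(grid$dz == 0 & grid$dy == 0 & grid$dx == 0), ]
  pos <- grid$dz > 0 | (grid$dz == 0 & (grid$dy > 0 | (grid$dy == 0 & grid$dx > 0)))
  as.matrix(grid[pos, , drop = FALSE])
}

#' Label connected components of a 3D mask
#'
#' Components are found on the voxel adjacency graph (26-, 6-, or per-slice
#' 8-connectivity) and numbered in decreasing size order, so component 1 is
#' always the largest.
#'
#' @param mask Logical 3D array.
#' @param connectivity 26 (default), 6, or 8 (in-plane only).
#' @return List with `labels` (integer array, 0 = background, 1 = largest
#'   component, ...), `sizes` (voxel counts per component), `n` components.
#' @export
label_components <- function(mask, connectivity = 26) {
  mask <- as_mask(mask)
  dims <- dim(mask)
  idx <- which(mask)
  out <- array(0L, dims)
  if (length(idx) == 0L) return(list(labels = out, sizes = integer(0), n = 0L))
  coords <- arrayInd(idx, dims)
  offs <- neighbour_offsets(connectivity)
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(offs))) {
    nb <- coords + matrix(offs[k, ], nrow(coords), 3L, byrow = TRUE)
    ok <- nb[, 1L] >= 1L & nb[, 1L] <= dims[1L] &
          nb[, 2L] >= 1L & nb[, 2L] <= dims[2L] &
          nb[, 3L] >= 1L & nb[, 3L] <= dims[3L]
    nb_lin <- (nb[ok, 3L] - 1L) * dims[1L] * dims[2L] +
              (nb[ok, 2L] - 1L) * dims[1L] + nb[ok, 1L]
    hit <- match(nb_lin, idx)
    found <- !is.na(hit)
    from <- c(from, which(ok)[found])
    to <- c(to, hit[found])
  }
  g <- igraph::make_graph(rbind(from, to), n = length(idx), directed = FALSE)
  comp <- igraph::components(g)
  ord <- order(comp$csize, decreasing = TRUE)
  relabel <- integer(comp$no)
  relabel[ord] <- seq_len(comp$no)
  out[idx] <- relabel[comp$membership]
  list(labels = out, sizes = as.integer(comp$csize[ord]), n = comp$no)
}

#' Keep the largest connected component
#'
#' @inheritParams label_components
#' @return Logical array of the same shape.
#' @export
largest_component <- function(mask, connectivity = 26) {
  cc <- label_components(mask, connectivity)
  cc$labels == 1L
}

#' Fill in-plane holes of a 3D mask
#'
#' Background 4-connected to the slice border is preserved; enclosed
#' background is filled, independently per slice. Works on all slices at once
#' by iterated in-plane propagation of border-reachable background.
#'
#' @param mask Logical 3D array (z, y, x).
#' @return Logical array with per-slice holes filled.
#' @export
fill_holes_slicewise <- function(mask) {
  mask <- as_mask(mask)
  d <- dim(mask)
  bg <- !mask
  reach <- array(FALSE, d)
  reach[, c(1L, d[2L]), ] <- bg[, c(1L, d[2L]), ]
  reach[, , c(1L, d[3L])] <- reach[, , c(1L, d[3L])] | bg[, , c(1L, d[3L])]
  repeat {
    grown <- reach
    grown[, -1L, ] <- grown[, -1L, ] | reach[, -d[2L], ]
    grown[, -d[2L], ] <- grown[, -d[2L], ] | reach[, -1L, ]
    grown[, , -1L] <- grown[, , -1L] | reach[, , -d[3L]]
    grown[, , -d[3L]] <- grown[, , -d[3L]] | reach[, , -1L]
    grown <- grown & bg
    if (identical(grown, reach)) break
    reach <- grown
  }
  mask | (bg & !reach)
}

#' Dilate a mask by a physical radius
#'
#' Morphological dilation with an ellipsoidal structuring element whose
#' half-axes are `radius_mm` converted to voxels per axis, so anisotropic
#' spacing (e.g. thick CT slices) is respected. Implemented as an FFT
#' convolution with the structuring element followed by thresholding, which
#' is exact for binary input.
#'
#' @param mask Logical 3D array (z, y, x).
#' @param spacing Voxel spacing `c(dz, dy, dx)` in mm.
#' @param radius_mm Dilation radius in mm (>= 0).
#' @return Dilated logical array.
#' @export
dilate_mm <- function(mask, spacing, radius_mm) {
  mask <- as_mask(mask)
  if (length(spacing) != 3L || any(spacing <= 0)) abort_invalid("spacing must be 3 positive values")
  if (radius_mm < 0) abort_invalid("radius_mm must be >= 0")
  half <- floor(radius_mm / spacing)
  if (all(half == 0)) return(mask)
  se_dim <- 2L * half + 1L
  dz <- (-half[1L]:half[1L]) * spacing[1L]
  dy <- (-half[2L]:half[2L]) * spacing[2L]
  dx <- (-half[3L]:half[3L]) * spacing[3L]
  se <- outer(outer(dz^2, dy^2, "+"), dx^2, "+") <= radius_mm^2 + 1e-9
  conv3d_binary(mask, se) > 0.5
}

# Linear 3D convolution of a binary array with a small binary kernel via
# zero-padded FFT; returns the central (same-size) window with the kernel
# centred. Values are counts, so > 0.5 thresholds reliably.
conv3d_binary <- function(mask, kernel) {
  dm <- dim(mask); dk <- dim(kernel)
  pad <- mapply(function(n, m) stats::nextn(n + m - 1L, c(2, 3, 5)), dm, dk)
  a <- array(0, pad); b <- array(0, pad)
  a[seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3])] <- mask
  b[seq_len(dk[1]), seq_len(dk[2]), seq_len(dk[3])] <- kernel
  conv <- Re(stats::fft(stats::fft(a) * stats::fft(b), inverse = TRUE)) / prod(pad)
  half <- (dk - 1L) %/% 2L
  conv[half[1] + seq_len(dm[1]), half[2] + seq_len(dm[2]), half[3] + seq_len(dm[3])]
}

gaussian_kernel_matrix <- function(n, sigma) {
  # n x n smoothing operator: row i holds a normalised Gaussian centred at i,
  # truncated at 4 sigma; border rows renormalise over the in-range support.
  half <- max(1L, ceiling(4 * sigma))
  offs <- -half:half
  w <- exp(-offs^2 / (2 * sigma^2))
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + offs
    ok <- j >= 1L & j <= n
    K[i, j[ok]] <- w[ok] / sum(w[ok])
  }
  K
}

#' In-plane Gaussian blur of a volume
#'
#' Separable Gaussian smoothing applied within each axial slice only
#' (a simple partial-volume surrogate; slice thickness is typically much
#' larger than in-plane spacing, so through-plane blur is not modelled).
#'
#' @param voxels Numeric 3D array (z, y, x).
#' @param sigma Standard deviation in voxels; 0 returns the input.
#' @return Blurred array of the same shape.
#' @export
blur_inplane <- function(voxels, sigma) {
  if (sigma < 0) abort_invalid("sigma must be >= 0")
  if (sigma == 0) return(voxels)
  d <- dim(voxels)
  Ky <- gaussian_kernel_matrix(d[2L], sigma)
  Kx <- gaussian_kernel_matrix(d[3L], sigma)
  out <- voxels
  for (z in seq_len(d[1L])) {
    out[z, , ] <- Ky %*% voxels[z, , ] %*% t(Kx)
  }
  out
}

as_mask <- function(x) {
  if (is.list(x) && !is.null(x$mask)) x <- x$mask
  if (length(dim(x)) != 3L) abort_invalid("mask must be a 3D array")
  storage.mode(x) <- "logical"
  if (anyNA(x)) abort_invalid("mask must not contain NA")
  x
}
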
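# Separable Gaussian smoothing of 3-D volumes. FWHM is given in mm and
# converted per axis to a voxel-unit sigma; the discrete kernel is normalized
# to sum 1 and the boundary is handled by edge replication, so constant
# volumes are exactly invariant.

gauss_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# n x n smoothing matrix with replicate boundary: row i holds the kernel
# centred at i with out-of-range taps clamped to the edge sample.
smooth_matrix_1d <- function(n, sigma_vox) {
  k <- gauss_kernel_1d(sigma_vox)
  r <- (length(k) - 1L) / 2L
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- pmin(pmax(i + seq(-r, r), 1L), n)
    for (j in seq_along(idx)) S[i, idx[j]] <- S[i, idx[j]] + k[j]
  }
  S
}

FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))

#' Gaussian-smooth a GMV volume
#'
#' @param img `gmv_image` or numeric 3-D array.
#' @param fwhm_mm full-width-at-half-maximum of the Gaussian kernel in mm;
#'   0 is the identity.
#' @param voxel_size_mm used when `img` is a bare array.
#' @return same type as `img`.
#' @export
smooth_gmv <- function(img, fwhm_mm, voxel_size_mm = 3) {
  if (!is_scalar_num(fwhm_mm) || fwhm_mm < 0) stopf("fwhm_mm must be >= 0")
  is_img <- inherits(img, "gmv_image")
  a <- if (is_img) img$data else img
  vs <- if (is_img) img$voxel_size_mm else rep_len(voxel_size_mm, 3L)
  if (fwhm_mm > 0) {
    dims <- dim(a)
    for (ax in 1:3) {
      sigma_vox <- fwhm_mm * FWHM_TO_SIGMA / vs[ax]
      S <- smooth_matrix_1d(dims[ax], sigma_vox)
      a <- apply_axis(a, ax, S)
    }
  }
  if (is_img) gmv_image(a, img$affine, img$voxel_size_mm) else a
}

# multiply matrix S along axis `ax` of 3-D array `a`
apply_axis <- function(a, ax, S) {
  d <- dim(a)
  perm <- c(ax, setdiff(1:3, ax))
  m <- matrix(aperm(a, perm), nrow = d[ax])
  m <- S %*% m
  out <- array(m, dim = d[perm])
  aperm(out, order(perm))
}

#' Smooth a subject-by-feature matrix through volume space
#'
#' Rebuilds each row as a volume on the mask grid (out-of-mask voxels 0),
#' smooths it, and re-extracts the masked features. Smoothing has no fitted
#' parameters, so this is leakage-free and precomputable per FWHM level.
#'
#' @param X `[n x p]` matrix in canonical mask ordering.
#' @param mask `voxel_mask`.
#' @param fwhm_mm kernel width in mm.
#' @return matrix of the same shape.
#' @export
smooth_feature_matrix <- function(X, mask, fwhm_mm) {
  if (fwhm_mm == 0) return(X)
  out <- X
  vol <- array(0, dim = dim(mask$mask))
  for (i in seq_len(nrow(X))) {
    vol[] <- 0
    vol[mask$ordering] <- X[i, ]
    sm <- smooth_gmv(vol, fwhm_mm, voxel_size_mm = mask$voxel_size_mm)
    out[i, ] <- sm[mask$ordering]
  }
  out
}
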
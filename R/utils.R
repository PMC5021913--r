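# Internal helpers shared across the pipeline.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Commercial rounding (0.5 always rounds up for positive input), used by
#' [pooled_component_count()] where the cohort mean of two medians can land
#' exactly on a half integer. `base::round()` rounds half to even, which is
#' not the convention adopted here.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @keywords internal
round_half_up <- function(x) floor(x + 0.5)

# FWHM of a Gaussian = sqrt(8 ln 2) * sigma (used for smoothing kernels);
# the kernel-parameter estimators use the rounded factor 2.35 (see
# estimate_gammas) to match the field convention for resel-scaled distances.
FWHM_PER_SIGMA <- sqrt(8 * log(2))

# Discrete 1D Gaussian kernel truncated at +-4 sigma, renormalised.
gaussian_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  m <- max(1L, ceiling(4 * sigma))
  w <- exp(-((-m):m)^2 / (2 * sigma^2))
  w / sum(w)
}

# Separable Gaussian smoothing of a 3D array (sigma in voxels per axis).
# Boundaries are handled by renormalising the truncated kernel so that flat
# fields stay flat near the volume edge.
smooth_gaussian_3d <- function(arr, sigma_vox) {
  d <- dim(arr)
  stopifnot(length(d) == 3L, length(sigma_vox) == 3L)
  for (ax in 1:3) {
    if (sigma_vox[ax] <= 0 || d[ax] == 1L) next
    w <- gaussian_kernel_1d(sigma_vox[ax])
    m <- (length(w) - 1L) / 2L
    acc <- array(0, d)
    nrm <- array(0, d)
    for (j in seq_along(w)) {
      off <- j - m - 1L
      src <- seq_len(d[ax]) - off
      ok <- src >= 1L & src <= d[ax]
      if (!any(ok)) next
      idx_dst <- which(ok)
      idx_src <- src[ok]
      if (ax == 1L) {
        acc[idx_dst, , ] <- acc[idx_dst, , ] + w[j] * arr[idx_src, , ]
        nrm[idx_dst, , ] <- nrm[idx_dst, , ] + w[j]
      } else if (ax == 2L) {
        acc[, idx_dst, ] <- acc[, idx_dst, ] + w[j] * arr[, idx_src, ]
        nrm[, idx_dst, ] <- nrm[, idx_dst, ] + w[j]
      } else {
        acc[, , idx_dst] <- acc[, , idx_dst] + w[j] * arr[, , idx_src]
        nrm[, , idx_dst] <- nrm[, , idx_dst] + w[j]
      }
    }
    arr <- acc / nrm
  }
  arr
}

# Smooth every frame of a 4D array spatially.
smooth_gaussian_4d <- function(arr, sigma_vox) {
  d <- dim(arr)
  stopifnot(length(d) == 4L)
  for (t in seq_len(d[4])) {
    arr[, , , t] <- smooth_gaussian_3d(array(arr[, , , t], d[1:3]), sigma_vox)
  }
  arr
}

# voxel index matrix (n x 3, 1-based) for TRUE cells of a 3D logical array
mask_coords <- function(mask) {
  which(mask, arr.ind = TRUE)
}

# world (mm) coordinates of voxel index rows (1-based, no rotation: the
# synthetic volumes carry a diagonal affine)
voxel_to_mm <- function(ijk, voxel_size_mm) {
  sweep(ijk - 1, 2, voxel_size_mm, `*`)
}
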
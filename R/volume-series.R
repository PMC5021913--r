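#' 4D volume time series
#'
#' Container for a 4D scalar field (three spatial axes plus time) with voxel
#' size in mm and a binary domain (brain/cortex) mask. All pipeline stages
#' consume and produce this type. Single-slice (2D) data are stored as 3D
#' with a singleton third axis so that the same code path handles both.
#'
#' @param data numeric 4D array `(x, y, z, t)`. A 3D array `(x, y, t)` is
#'   promoted to 4D with a singleton z axis.
#' @param voxel_size_mm positive numeric length-3 vector, mm per voxel along
#'   each spatial axis.
#' @param mask logical/0-1 3D array matching the spatial shape of `data`;
#'   `NULL` means all voxels are in the domain.
#' @param fwhm_mm optional length-3 vector recording the spatial smoothness
#'   (applied or estimated) in mm.
#' @return an object of class `"volume_series"`: a list with elements
#'   `data`, `voxel_size_mm`, `mask`, `fwhm_mm`.
#' @examples
#' vs <- volume_series(array(rnorm(4 * 4 * 2 * 10), c(4, 4, 2, 10)),
#'                     voxel_size_mm = c(3, 3, 3))
#' dim(vs$data)
#' @export
volume_series <- function(data, voxel_size_mm, mask = NULL, fwhm_mm = NULL) {
  if (length(dim(data)) == 3L) {
    d <- dim(data)
    data <- array(data, c(d[1], d[2], 1L, d[3]))
    if (!is.null(mask) && length(dim(mask)) == 2L)
      mask <- array(mask, c(dim(mask), 1L))
  }
  d <- dim(data)
  if (length(d) != 4L)
    stop("`data` must be a 4D (x, y, z, t) array")
  if (d[4] < 2L)
    stop("need at least 2 time points")
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop("`voxel_size_mm` must be 3 positive values")
  if (is.null(mask)) {
    mask <- array(TRUE, d[1:3])
  } else {
    mask <- array(as.logical(mask), dim(mask))
    if (!identical(dim(mask), d[1:3]))
      stop("mask shape must equal the spatial shape of `data`")
  }
  structure(list(data = data, voxel_size_mm = voxel_size_mm, mask = mask,
                 fwhm_mm = fwhm_mm),
            class = "volume_series")
}

#' @export
print.volume_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("volume_series: %d x %d x %d voxels, %d time points\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  voxel size: %s mm; in-mask voxels: %d\n",
              paste(signif(x$voxel_size_mm, 4), collapse = " x "),
              sum(x$mask)))
  if (!is.null(x$fwhm_mm))
    cat(sprintf("  smoothness (FWHM): %s mm\n",
                paste(signif(x$fwhm_mm, 4), collapse = ", ")))
  invisible(x)
}

#' Extract the in-mask voxel-by-time matrix
#'
#' @param vs a [volume_series()].
#' @return list with `series` (n voxels x T matrix), `ijk` (n x 3 voxel
#'   indices, 1-based) and `coords_mm` (n x 3 world coordinates).
#' @export
mask_series <- function(vs) {
  d <- dim(vs$data)
  flat <- matrix(vs$data, prod(d[1:3]), d[4])
  keep <- which(vs$mask)
  ijk <- mask_coords(vs$mask)
  list(series = flat[keep, , drop = FALSE],
       ijk = ijk,
       coords_mm = voxel_to_mm(ijk, vs$voxel_size_mm))
}

#' Read a 4D NIfTI plus mask into a volume_series
#'
#' @param data_path path to the 4D NIfTI image.
#' @param mask_path optional path to a 3D binary NIfTI mask.
#' @param fwhm_mm optional known smoothness in mm.
#' @return a [volume_series()].
#' @export
read_volume_series <- function(data_path, mask_path = NULL, fwhm_mm = NULL) {
  img <- RNifti::readNifti(data_path)
  pd <- attr(img, "pixdim") %||% RNifti::pixdim(img)
  vox <- abs(as.numeric(pd[1:3]))
  vox[!is.finite(vox) | vox == 0] <- 1
  mask <- NULL
  if (!is.null(mask_path)) {
    m <- RNifti::readNifti(mask_path)
    mask <- array(as.array(m) != 0, dim(m)[1:3])
  }
  arr <- as.array(img)
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  volume_series(arr, voxel_size_mm = vox, mask = mask, fwhm_mm = fwhm_mm)
}

#' Write a volume_series (and mask) as NIfTI
#'
#' @param vs a [volume_series()].
#' @param prefix output path prefix; writes `<prefix>.nii.gz` and
#'   `<prefix>_mask.nii.gz`.
#' @return invisibly, the paths written.
#' @export
write_volume_series <- function(vs, prefix) {
  dp <- paste0(prefix, ".nii.gz")
  mp <- paste0(prefix, "_mask.nii.gz")
  img <- RNifti::asNifti(vs$data)
  RNifti::pixdim(img) <- c(vs$voxel_size_mm, 1)
  RNifti::writeNifti(img, dp)
  msk <- RNifti::asNifti(array(as.integer(vs$mask), dim(vs$mask)))
  RNifti::pixdim(msk) <- vs$voxel_size_mm
  RNifti::writeNifti(msk, mp)
  invisible(c(data = dp, mask = mp))
}

#' Write an integer label volume as NIfTI
#'
#' @param labels 3D integer array (0 = background).
#' @param voxel_size_mm length-3 voxel size.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_label_volume <- function(labels, voxel_size_mm, path) {
  img <- RNifti::asNifti(array(as.integer(labels), dim(labels)))
  RNifti::pixdim(img) <- voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}
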
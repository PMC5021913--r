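# Synthetic benchmark generators: block-design regressors, the hybrid
# activation slice (64 x 64, 140 frames, 5 x 5 activation square inside a
# ~1212-voxel disk "brain"), and 3D multi-ROI network phantoms with shared
# latent time courses.

#' Block-design specification
#'
#' @param on_seconds,off_seconds durations of ON and OFF periods (s).
#' @param n_blocks number of ON blocks in the run.
#' @param tr_seconds repetition time (s).
#' @param total_seconds total run duration (s); the regressor has
#'   `floor(total/tr)` samples.
#' @return an object of class `"block_design"`.
#' @examples
#' block_design(30, 15, 6, 2.5, 285)  # 114 frames, six 12-frame ON blocks
#' @export
block_design <- function(on_seconds, off_seconds, n_blocks, tr_seconds,
                         total_seconds) {
  stopifnot(on_seconds > 0, off_seconds > 0, n_blocks >= 0, tr_seconds > 0,
            total_seconds > 0)
  if (n_blocks * (on_seconds + off_seconds) > total_seconds + 1e-9)
    stop("n_blocks * (on + off) exceeds total_seconds")
  structure(list(on_seconds = on_seconds, off_seconds = off_seconds,
                 n_blocks = as.integer(n_blocks), tr_seconds = tr_seconds,
                 total_seconds = total_seconds),
            class = "block_design")
}

#' Sampled 0/1 block regressor
#'
#' Builds the stimulation indicator sampled at the TR. ON and OFF periods
#' either strictly alternate (default) or are placed in seeded random order
#' under the constraint that ON blocks never merge, so the regressor always
#' contains exactly `n_blocks` contiguous ON runs.
#'
#' @param design a [block_design()].
#' @param order `"alternate"` or `"random"`.
#' @param seed integer seed used when `order = "random"`.
#' @param ratio `"round"` rounds non-integral block/TR ratios to the nearest
#'   number of frames; `"strict"` rejects them.
#' @return integer vector of 0/1 of length `floor(total/tr)`.
#' @examples
#' r <- block_regressor(block_design(30, 15, 6, 2.5, 285))
#' length(r); sum(r)
#' @export
block_regressor <- function(design, order = c("alternate", "random"),
                            seed = NULL, ratio = c("round", "strict")) {
  order <- match.arg(order)
  ratio <- match.arg(ratio)
  n_t <- floor(design$total_seconds / design$tr_seconds)
  if (design$n_blocks == 0L) return(integer(n_t))
  on_f <- design$on_seconds / design$tr_seconds
  off_f <- design$off_seconds / design$tr_seconds
  if (ratio == "strict" &&
      (abs(on_f - round(on_f)) > 1e-9 || abs(off_f - round(off_f)) > 1e-9))
    stop("block durations are not integer multiples of the TR")
  on_n <- max(1L, round(on_f))
  off_n <- max(1L, round(off_f))
  nb <- design$n_blocks
  if (order == "alternate") {
    x <- rep(rep(c(1L, 0L), nb), times = rep(c(on_n, off_n), nb))
  } else {
    if (!is.null(seed)) set.seed(seed)
    # place nb ON and nb OFF periods in random order, rejecting layouts in
    # which two ON periods would touch and merge
    repeat {
      slots <- sample(rep(c(1L, 0L), each = nb))
      if (!any(slots[-1] == 1L & slots[-2 * nb] == 1L)) break
    }
    x <- rep(slots, times = ifelse(slots == 1L, on_n, off_n))
  }
  if (length(x) >= n_t) x[seq_len(n_t)] else c(x, integer(n_t - length(x)))
}

#' Canonical double-gamma haemodynamic response function
#'
#' SPM-convention double gamma: peak at 6 s, undershoot at 16 s with ratio
#' 1/6, unit peak height.
#'
#' @param t_seconds time points (s) at which to evaluate the response.
#' @return numeric vector of the HRF sampled at `t_seconds`.
#' @export
hrf_double_gamma <- function(t_seconds) {
  t <- pmax(t_seconds, 0)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

# Convolve a 0/1 regressor with the canonical HRF at the TR; unit peak.
convolve_hrf <- function(regressor, tr_seconds) {
  h <- hrf_double_gamma(seq(0, 32, by = tr_seconds))
  y <- stats::convolve(regressor, rev(h), type = "open")[seq_along(regressor)]
  m <- max(abs(y))
  if (m > 0) y / m else y
}

#' Activation specification
#'
#' A set of voxels sharing one activation time course at a given
#' contrast-to-noise ratio (CNR = contrast amplitude / background noise sd).
#'
#' @param region_voxels integer matrix (n x 3) of 1-based voxel indices.
#' @param time_course numeric vector (length T), unit contrast amplitude.
#' @param cnr nonnegative contrast-to-noise ratio.
#' @return object of class `"activation_spec"`.
#' @export
activation_spec <- function(region_voxels, time_course, cnr) {
  region_voxels <- matrix(as.integer(region_voxels), ncol = 3)
  if (nrow(region_voxels) == 0L) stop("empty activation region")
  if (cnr < 0) stop("cnr must be nonnegative")
  structure(list(region_voxels = region_voxels,
                 time_course = as.numeric(time_course), cnr = cnr),
            class = "activation_spec")
}

# Disk mask of exactly 1212 voxels on the 64 x 64 grid (slightly off-centre
# so the lattice count lands on the published in-brain voxel count).
hybrid_disk_mask <- function(shape = c(64L, 64L)) {
  x <- matrix(seq_len(shape[1]), shape[1], shape[2])
  y <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  (x - 32.3)^2 + (y - 32.7)^2 <= 19.65^2
}

# Default 5 x 5 activation square, off-centre but well inside the disk.
hybrid_square <- function() {
  as.matrix(expand.grid(x = 36:40, y = 36:40, z = 1L))
}

# Low-frequency nuisance time course: a random-phase cosine at `cycles`
# periods per run, standardised to unit sd. Distinct integer cycle counts
# give mutually orthogonal drift components, so the background component
# spectrum follows the chosen amplitude ladder.
slow_drift_course <- function(n_t, cycles = 1) {
  tt <- seq_len(n_t)
  y <- cos(2 * pi * cycles * tt / n_t + stats::runif(1, 0, 2 * pi))
  as.numeric(scale(y))
}

#' Generate a hybrid activation slice
#'
#' Emulates the hybrid benchmark: a single 64 x 64 slice, 140 frames, with a
#' 5 x 5 pixel activation square superimposed at a controlled
#' contrast-to-noise ratio on an fMRI-like background restricted to a
#' disk-shaped "brain" mask of 1212 voxels.
#'
#' The real base slice of the published benchmark is unavailable, so the
#' background is synthesised to carry the two properties of resting EPI data
#' that the downstream stages rely on: (i) thermal noise with a modest
#' intrinsic spatial smoothness (default FWHM 2 voxels, typical of the
#' effective point-spread of EPI reconstruction) and (ii) a ladder of
#' spatially smooth, temporally slow structured components (scanner drift /
#' physiological surrogates) whose amplitudes decay so that the activation
#' eigenvalue falls among the leading components, as in the published
#' benchmark runs. The per-voxel background standard deviation is rescaled
#' to `noise_sd`, so `cnr` is defined against the total background
#' fluctuation, as in the original benchmark where noise was measured within
#' a cortical region. See the methods vignette for the full rationale.
#'
#' @param cnr contrast-to-noise ratio of the activation square (the
#'   published levels are 1.33, 1.66 and 2).
#' @param seed integer seed; identical seed and parameters give bit-identical
#'   output.
#' @param shape 2D extent (default `c(64, 64)`).
#' @param n_time number of frames (default 140).
#' @param spec optional [activation_spec()]; by default a 5 x 5 square with
#'   an HRF-convolved alternating block time course (10 frames ON / 10 OFF).
#' @param noise_sd background standard deviation.
#' @param waveform `"hrf"` (block regressor convolved with the canonical
#'   double-gamma HRF) or `"boxcar"` for the default activation time course.
#' @param voxel_size_mm voxel size; default `c(3.125, 3.125, 6)` mm
#'   (64 voxels over a 200 mm field of view).
#' @param noise_fwhm_vox intrinsic spatial smoothness of the thermal noise
#'   (FWHM, voxels).
#' @param struct_amp amplitudes of the structured background components
#'   relative to the thermal-noise sd; their spatial maps are smooth random
#'   fields (FWHM `struct_fwhm_vox` voxels).
#' @param struct_fwhm_vox smoothness of the structured component maps.
#' @return list with elements `vs` (a [volume_series()]), `truth` (3D 0/1
#'   label array), `spec` (the activation specification used), `regressor`
#'   (the 0/1 block indicator) and `params`.
#' @examples
#' h <- generate_hybrid_slice(cnr = 2, seed = 1)
#' sum(h$vs$mask)   # 1212
#' sum(h$truth)     # 25
#' @export
generate_hybrid_slice <- function(cnr, seed, shape = c(64L, 64L),
                                  n_time = 140L, spec = NULL, noise_sd = 1,
                                  waveform = c("hrf", "boxcar"),
                                  voxel_size_mm = c(3.125, 3.125, 6),
                                  noise_fwhm_vox = 2,
                                  struct_amp = c(1, 0.7, 0.5, 0.3, 0.15, 0.12),
                                  struct_fwhm_vox = 12) {
  waveform <- match.arg(waveform)
  stopifnot(cnr >= 0, noise_sd > 0)
  set.seed(seed)
  design <- block_design(on_seconds = 25, off_seconds = 25, n_blocks = 7,
                         tr_seconds = 2.5, total_seconds = n_time * 2.5)
  regressor <- block_regressor(design)
  if (is.null(spec)) {
    tc <- if (waveform == "hrf") convolve_hrf(regressor, 2.5) else regressor
    spec <- activation_spec(hybrid_square(), tc, cnr)
  }
  if (length(spec$time_course) != n_time)
    stop("activation time course length must equal n_time")
  if (identical(as.integer(shape), c(64L, 64L))) {
    mask2d <- hybrid_disk_mask(shape)
  } else {
    mask2d <- matrix(TRUE, shape[1], shape[2])
  }
  if (any(spec$region_voxels[, 1] > shape[1] |
            spec$region_voxels[, 2] > shape[2]))
    stop("activation region outside the volume")

  sig <- noise_fwhm_vox / FWHM_PER_SIGMA
  noise <- array(stats::rnorm(shape[1] * shape[2] * n_time),
                 c(shape[1], shape[2], 1L, n_time))
  if (noise_fwhm_vox > 1e-8)
    noise <- smooth_gaussian_4d(noise, c(sig, sig, 0))
  flat <- matrix(noise, shape[1] * shape[2], n_time)
  flat <- flat / stats::sd(flat[mask2d, ])

  for (k in seq_along(struct_amp)) {
    map <- smooth_gaussian_3d(array(stats::rnorm(shape[1] * shape[2]),
                                    c(shape, 1L)),
                              c(struct_fwhm_vox, struct_fwhm_vox, 0) /
                                FWHM_PER_SIGMA)
    map <- map / stats::sd(map[mask2d])
    flat <- flat + struct_amp[k] * as.numeric(map) %o%
      slow_drift_course(n_time, cycles = k)
  }
  # rescale so the pooled in-mask background sd equals noise_sd
  flat <- flat * (noise_sd / stats::sd(flat[mask2d, ]))

  act_lin <- spec$region_voxels[, 1] + (spec$region_voxels[, 2] - 1L) * shape[1]
  flat[act_lin, ] <- flat[act_lin, ] +
    spec$cnr * noise_sd * rep(spec$time_course, each = length(act_lin))
  flat[!mask2d, ] <- 0

  truth <- array(0L, c(shape, 1L))
  truth[act_lin] <- 1L
  vs <- volume_series(array(flat, c(shape, 1L, n_time)),
                      voxel_size_mm = voxel_size_mm,
                      mask = array(mask2d, c(shape, 1L)))
  list(vs = vs, truth = truth, spec = spec, regressor = regressor,
       params = list(cnr = cnr, seed = seed, noise_sd = noise_sd,
                     waveform = waveform, noise_fwhm_vox = noise_fwhm_vox,
                     struct_amp = struct_amp,
                     struct_fwhm_vox = struct_fwhm_vox))
}

#' Generate a 3D block-design network phantom
#'
#' Builds a 3D volume containing several spatially compact ROIs whose time
#' courses are stated mixtures of shared latent sources, plus Gaussian noise,
#' optionally Gaussian-smoothed. Because the source-sharing structure is
#' known, the phantom carries ground truth for every pipeline stage: voxel
#' selection, clustering and clique-network extraction.
#'
#' @param shape 3D extent in voxels.
#' @param n_time number of frames.
#' @param rois list of ROI descriptors; each a list with `voxels` (n x 3
#'   integer matrix), `mixing` (length-S weights over the latent sources) and
#'   `cnr` (contrast-to-noise ratio of the mixed time course).
#' @param sources T x S matrix of latent time courses (unit amplitude).
#' @param noise_sd Gaussian noise sd (before smoothing).
#' @param fwhm_mm length-3 smoothing FWHM in mm applied to the noisy data
#'   (0 = none).
#' @param voxel_size_mm voxel size in mm.
#' @param seed integer seed.
#' @return list with `vs` (a [volume_series()]), `truth` (3D integer label
#'   array, 0 background), `roi_sources` (ROI x source 0/1 incidence),
#'   `truth_adjacency` (ROI x ROI, 1 where two ROIs share a source) and
#'   `sources`.
#' @export
generate_network_phantom <- function(shape, n_time, rois, sources,
                                     noise_sd = 1, fwhm_mm = c(0, 0, 0),
                                     voxel_size_mm = c(3, 3, 3), seed = 1) {
  stopifnot(length(shape) == 3L, n_time == nrow(sources))
  set.seed(seed)
  truth <- array(0L, shape)
  for (i in seq_along(rois)) {
    v <- rois[[i]]$voxels
    if (any(v < 1L) || any(sweep(v, 2, shape, `>`)))
      stop("ROI voxels outside the volume")
    lin <- v[, 1] + (v[, 2] - 1L) * shape[1] + (v[, 3] - 1L) * shape[1] * shape[2]
    if (any(truth[lin] != 0L)) stop("overlapping ROIs")
    truth[lin] <- i
  }
  arr <- array(stats::rnorm(prod(shape) * n_time, sd = noise_sd),
               c(shape, n_time))
  flat <- matrix(arr, prod(shape), n_time)
  roi_sources <- matrix(0L, length(rois), ncol(sources))
  for (i in seq_along(rois)) {
    mix <- rois[[i]]$mixing
    tc <- drop(sources %*% mix)
    m <- max(abs(tc))
    if (m > 0) tc <- tc / m
    lin <- which(as.integer(truth) == i)
    flat[lin, ] <- flat[lin, ] +
      rois[[i]]$cnr * noise_sd * rep(tc, each = length(lin))
    roi_sources[i, ] <- as.integer(abs(mix) > 1e-12)
  }
  arr <- array(flat, c(shape, n_time))
  if (any(fwhm_mm > 1e-8)) {
    sig <- fwhm_mm / FWHM_PER_SIGMA / voxel_size_mm
    arr <- smooth_gaussian_4d(arr, sig)
  }
  adj <- (roi_sources %*% t(roi_sources) > 0) * 1L
  diag(adj) <- 0L
  vs <- volume_series(arr, voxel_size_mm = voxel_size_mm,
                      fwhm_mm = if (any(fwhm_mm > 0)) fwhm_mm else NULL)
  list(vs = vs, truth = truth, roi_sources = roi_sources,
       truth_adjacency = adj, sources = sources)
}

#' Default 3D network phantom
#'
#' The stock end-to-end test surface: an 18 x 18 x 8 volume (3 mm isotropic
#' voxels, 140 frames at TR 2.5 s) with five 3 x 3 x 2 ROIs. ROIs 1-3 share
#' latent source 1 and ROIs 4-5 share source 2, so the ground-truth
#' connectivity network is a 3-clique plus a 2-clique. Sources are
#' HRF-convolved block designs (30 s ON / 15 s OFF and a phase-shifted
#' 25 s / 20 s design). Noise is white with mild reconstruction smoothing
#' (FWHM 2.8 mm, just under one voxel), keeping background voxel pairs
#' clearly below the correlation-significance threshold while leaving the
#' estimated resel scale above the voxel spacing.
#'
#' @param seed integer seed.
#' @param cnr per-ROI contrast-to-noise ratio (default 2.5, a strong
#'   block-design response).
#' @param fwhm_mm applied smoothing FWHM in mm.
#' @return as [generate_network_phantom()].
#' @export
default_network_phantom <- function(seed = 1, cnr = 2.5,
                                    fwhm_mm = c(6, 6, 6)) {
  n_time <- 140L
  d1 <- block_design(30, 15, 6, 2.5, 285)
  s1 <- convolve_hrf(c(block_regressor(d1), integer(n_time - 114L)), 2.5)
  d2 <- block_design(15, 20, 10, 2.5, n_time * 2.5)
  r2 <- block_regressor(d2)
  r2 <- c(integer(4L), r2)[seq_len(n_time)]  # 10 s phase shift
  s2 <- convolve_hrf(r2, 2.5)
  sources <- cbind(s1, s2)
  box <- function(x0, y0, z0)
    as.matrix(expand.grid(x = x0:(x0 + 2L), y = y0:(y0 + 2L),
                          z = z0:(z0 + 1L)))
  rois <- list(
    list(voxels = box(2L, 2L, 2L),  mixing = c(1, 0), cnr = cnr),
    list(voxels = box(12L, 3L, 2L), mixing = c(1, 0), cnr = cnr),
    list(voxels = box(7L, 12L, 6L), mixing = c(1, 0), cnr = cnr),
    list(voxels = box(3L, 13L, 3L), mixing = c(0, 1), cnr = cnr),
    list(voxels = box(13L, 12L, 6L), mixing = c(0, 1), cnr = cnr))
  generate_network_phantom(shape = c(18L, 18L, 8L), n_time = n_time,
                           rois = rois, sources = sources, noise_sd = 1,
                           fwhm_mm = fwhm_mm, voxel_size_mm = c(3, 3, 3),
                           seed = seed)
}

#' Write a generated dataset (data, mask, truth labels, parameters) to disk
#'
#' @param gen output of [generate_hybrid_slice()] or
#'   [generate_network_phantom()].
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
write_generated <- function(gen, prefix) {
  p <- write_volume_series(gen$vs, prefix)
  tp <- paste0(prefix, "_truth.nii.gz")
  write_label_volume(gen$truth, gen$vs$voxel_size_mm, tp)
  jp <- paste0(prefix, "_params.json")
  jsonlite::write_json(gen$params %||% list(), jp, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(p, truth = tp, params = jp))
}
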
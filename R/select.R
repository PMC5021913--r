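# Select step: multiscale correlation analysis (MSCA).
#
# A coarse, resel-scale correlation pass over two shifted downsampling grids
# picks up blocks of voxels involved in significant connectivity; the union
# of the two coarse masks is then screened at acquisition scale, and voxels
# with at least one significant fine-scale connection survive.

#' Estimate spatial smoothness (FWHM) from the data
#'
#' Per-axis smoothness of the residual field (each voxel's time series after
#' removal of its temporal mean, standardised to unit variance), using the
#' random-field relation `FWHM_k = sqrt(4 ln 2 / lambda_k)` where `lambda_k`
#' is the variance of the forward difference of the standardised residuals
#' along axis `k`. Intended for unsmoothed data where the applied kernel is
#' unknown; estimates are clipped below at 1 voxel.
#'
#' @param vs a [volume_series()].
#' @return numeric length-3 vector of FWHM in mm, with attribute
#'   `"fwhm_vox"` (voxels).
#' @examples
#' vs <- volume_series(array(rnorm(8 * 8 * 4 * 20), c(8, 8, 4, 20)), c(3, 3, 3))
#' estimate_fwhm(vs)  # about one voxel for white noise
#' @export
estimate_fwhm <- function(vs) {
  d <- dim(vs$data)
  if (d[4] < 3L) stop("need at least 3 time points to estimate smoothness")
  if (sum(vs$mask) < 2L) stop("mask is (nearly) empty")
  flat <- matrix(vs$data, prod(d[1:3]), d[4])
  mu <- rowMeans(flat)
  sdv <- sqrt(pmax(rowSums((flat - mu)^2) / (d[4] - 1), 0))
  keep <- vs$mask & array(sdv > 0, d[1:3])
  if (!all(keep[vs$mask]))
    warning("constant in-mask voxels excluded from smoothness estimation")
  if (sum(keep) < 2L) stop("no variable in-mask voxels")
  res <- (flat - mu) / ifelse(sdv > 0, sdv, 1)

  lin <- array(seq_len(prod(d[1:3])), d[1:3])
  strides <- c(1L, d[1], d[1] * d[2])
  fwhm_vox <- numeric(3)
  for (ax in 1:3) {
    ok <- array(FALSE, d[1:3])
    idx <- slice.index(ok, ax)
    ok[] <- idx < d[ax]
    a <- lin[ok & keep]
    a <- a[keep[a + strides[ax]]]
    if (length(a) < 2L) {
      warning(sprintf("axis %d: too few in-mask neighbour pairs; FWHM set to 1 voxel", ax))
      fwhm_vox[ax] <- 1
      next
    }
    dif <- res[a + strides[ax], , drop = FALSE] - res[a, , drop = FALSE]
    lambda <- mean(dif^2)  # residuals have unit variance by construction
    fwhm_vox[ax] <- max(1, sqrt(4 * log(2) / lambda))
  }
  out <- fwhm_vox * vs$voxel_size_mm
  attr(out, "fwhm_vox") <- fwhm_vox
  out
}

#' Coarse downsampling grid
#'
#' @param block_shape_voxels length-3 positive integers: resel size in fine
#'   voxels per axis.
#' @param offset_voxels length-3 integers in `[0, block - 1]`: grid shift.
#' @return object of class `"coarse_grid"`.
#' @export
coarse_grid <- function(block_shape_voxels, offset_voxels = c(0L, 0L, 0L)) {
  b <- as.integer(block_shape_voxels)
  o <- as.integer(offset_voxels)
  stopifnot(length(b) == 3L, all(b >= 1L), length(o) == 3L,
            all(o >= 0L), all(o < b))
  structure(list(block = b, offset = o), class = "coarse_grid")
}

# Resel-scale block shape: FWHM in voxels, rounded, minimum 1 per axis.
resel_block <- function(fwhm_mm, voxel_size_mm) {
  pmax(1L, as.integer(round(fwhm_mm / voxel_size_mm)))
}

#' Coarse-voxel mean time series
#'
#' Averages the series of in-mask fine voxels within each grid block. Every
#' block containing at least one in-mask voxel yields a coarse voxel; empty
#' blocks are dropped.
#'
#' @param vs a [volume_series()].
#' @param grid a [coarse_grid()].
#' @return list with `series` (coarse voxels x T), `block_id` (3D integer
#'   array mapping each fine voxel to its coarse voxel row, NA outside the
#'   mask), `n_fine` (in-mask voxels per coarse voxel) and `centroid_mm`
#'   (mean world coordinates of each coarse voxel's members).
#' @export
coarse_series <- function(vs, grid) {
  d <- dim(vs$data)
  if (!any(vs$mask)) stop("empty mask")
  ijk <- mask_coords(vs$mask)
  bidx <- sweep(sweep(ijk - 1L, 2, grid$offset, `+`), 2,
                grid$block, function(i, b) i %/% b)
  key <- bidx[, 1] + 4096L * (bidx[, 2] + 4096L * bidx[, 3])
  fac <- match(key, sort(unique(key)))
  flat <- matrix(vs$data, prod(d[1:3]), d[4])[which(vs$mask), , drop = FALSE]
  m <- max(fac)
  agg <- rowsum(flat, fac)
  n_fine <- tabulate(fac, nbins = m)
  series <- agg / n_fine
  block_id <- array(NA_integer_, d[1:3])
  block_id[which(vs$mask)] <- fac
  centroid <- rowsum(voxel_to_mm(ijk, vs$voxel_size_mm), fac) / n_fine
  list(series = series, block_id = block_id, n_fine = n_fine,
       centroid_mm = centroid)
}

#' Significant pairwise correlations
#'
#' Computes Pearson correlations between all pairs of series, transforms each
#' to `t = r * sqrt((T-2) / (1-r^2))` with `T - 2` degrees of freedom (or a
#' Fisher-z normal approximation), applies a multiple-comparison correction
#' over the number of tested pairs, and keeps the pairs whose corrected
#' p-value is below `alpha`. Nodes with fewer surviving edges than
#' `min_connections` are then removed, together with their edges (applied
#' once, not iterated).
#'
#' @param series numeric matrix, one series per row (n x T).
#' @param alpha significance level in (0, 1).
#' @param correction `"bonferroni"` or `"fdr"` (Benjamini-Hochberg).
#' @param min_connections minimum number of significant edges a node must
#'   have to be kept (4 at the coarse scale per the outlier rule; 1 at the
#'   fine scale).
#' @param method `"t"` for the exact t distribution of the transformed
#'   correlation, `"fisher-z"` for the normal approximation.
#' @param coords_mm optional n x 3 matrix of node coordinates. When given
#'   together with `baseline = "distance"`, the smoothing-induced component
#'   of the correlations is removed before testing: pairs are binned by
#'   spatial distance and the per-bin median correlation (a robust estimate
#'   of the baseline induced by spatial smoothing, since true connectivity
#'   is sparse) is subtracted from `r`. For spatially uncorrelated data the
#'   baseline is near zero and the procedure reduces to the plain test.
#' @param baseline `"none"` (plain test of r against 0) or `"distance"`
#'   (test against the distance-binned empirical baseline).
#' @param baseline_min_pairs minimum pairs per distance bin for a baseline
#'   estimate (smaller bins use baseline 0).
#' @return object of class `"pair_graph"`: list with `nodes` (kept node
#'   indices), `edges` (m x 2 matrix of node index pairs, i < j), `r`, `p_adj`
#'   (per kept edge), `degree` (per kept node), `alpha`, `correction`,
#'   `n_tests`.
#' @export
significant_pairs <- function(series, alpha = 0.05,
                              correction = c("bonferroni", "fdr"),
                              min_connections = 1L,
                              method = c("t", "fisher-z"),
                              coords_mm = NULL,
                              baseline = c("none", "distance"),
                              baseline_min_pairs = 30L) {
  correction <- match.arg(correction)
  method <- match.arg(method)
  baseline <- match.arg(baseline)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  n <- nrow(series)
  n_t <- ncol(series)
  if (n < 2L) stop("need at least 2 series")
  if (n_t < 4L) stop("need at least 4 time points")
  sds <- apply(series, 1, stats::sd)
  live <- sds > 0
  if (!all(live)) warning(sum(!live), " zero-variance series excluded")
  cm <- matrix(NA_real_, n, n)
  if (sum(live) >= 2L)
    cm[live, live] <- stats::cor(t(series[live, , drop = FALSE]))
  ut <- which(upper.tri(cm), arr.ind = TRUE)
  r <- cm[ut]
  ok <- !is.na(r)
  ut <- ut[ok, , drop = FALSE]
  r <- pmin(pmax(r[ok], -1), 1)
  n_tests <- length(r)
  if (baseline == "distance") {
    if (is.null(coords_mm)) stop("distance baseline requires `coords_mm`")
    dd <- sqrt(rowSums((coords_mm[ut[, 1], , drop = FALSE] -
                          coords_mm[ut[, 2], , drop = FALSE])^2))
    bin <- round(dd * 2) / 2  # half-millimetre bins
    med <- tapply(r, bin, stats::median)
    cnt <- tapply(r, bin, length)
    base <- med[as.character(bin)]
    base[is.na(base) | cnt[as.character(bin)] < baseline_min_pairs] <- 0
    base <- pmax(as.numeric(base), 0)
    r <- pmin(pmax(r - base, -1), 1)
  }
  if (method == "t") {
    tt <- r * sqrt((n_t - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n_t - 2)
    p[abs(r) >= 1] <- 0
  } else {
    z <- atanh(pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)) * sqrt(n_t - 3)
    p <- 2 * stats::pnorm(-abs(z))
  }
  p_adj <- if (correction == "bonferroni") pmin(1, p * n_tests)
           else stats::p.adjust(p, method = "BH")
  sig <- p_adj < alpha
  edges <- ut[sig, , drop = FALSE]
  deg <- tabulate(edges, nbins = n)
  keep_node <- deg >= min_connections & deg > 0L
  keep_edge <- keep_node[edges[, 1]] & keep_node[edges[, 2]]
  edges_k <- edges[keep_edge, , drop = FALSE]
  structure(list(nodes = which(keep_node),
                 edges = matrix(c(pmin(edges_k[, 1], edges_k[, 2]),
                                  pmax(edges_k[, 1], edges_k[, 2])),
                                ncol = 2),
                 r = r[sig][keep_edge], p_adj = p_adj[sig][keep_edge],
                 degree = deg[keep_node], alpha = alpha,
                 correction = correction, n_tests = n_tests),
            class = "pair_graph")
}

#' @export
print.pair_graph <- function(x, ...) {
  cat(sprintf("pair_graph: %d nodes, %d significant edges (%s, alpha = %g, %d tests)\n",
              length(x$nodes), nrow(x$edges), x$correction, x$alpha, x$n_tests))
  invisible(x)
}

#' Multiscale correlation voxel selection
#'
#' Full Select step: (1) coarse-scale significance pass on the resel grid at
#' offset 0; (2) a second coarse pass with the grid shifted by 1 fine voxel
#' along every axis, recovering signal lost to the arbitrary initial grid
#' placement; (3) union of the two coarse binary masks, expanded to fine
#' voxels; (4) fine-scale significance pass restricted to that union;
#' (5) output mask = fine voxels with at least one significant connection.
#'
#' @param vs a [volume_series()].
#' @param alpha significance level used at both scales.
#' @param correction multiple-comparison procedure, see
#'   [significant_pairs()].
#' @param min_connections minimum significant-edge count at the coarse scale.
#' @param fwhm_mm smoothness used to size the resel blocks; `NULL` estimates
#'   it from the data via [estimate_fwhm()].
#' @param method correlation test, see [significant_pairs()].
#' @param baseline correlation baseline handling, see
#'   [significant_pairs()]; the default `"distance"` removes the
#'   smoothing-induced neighbour-correlation baseline at both scales (a
#'   no-op for spatially uncorrelated data).
#' @return list with `mask` (3D logical selection), `fine_graph` (a
#'   `pair_graph` whose nodes index rows of `fine_ijk`), `fine_ijk` (voxel
#'   indices screened at fine scale), `coarse_union` (3D logical), `fwhm_mm`
#'   and `block`.
#' @export
select_voxels <- function(vs, alpha = 0.05,
                          correction = c("bonferroni", "fdr"),
                          min_connections = 4L, fwhm_mm = NULL,
                          method = c("t", "fisher-z"),
                          baseline = c("distance", "none")) {
  correction <- match.arg(correction)
  method <- match.arg(method)
  baseline <- match.arg(baseline)
  if (is.null(fwhm_mm)) fwhm_mm <- vs$fwhm_mm %||% estimate_fwhm(vs)
  block <- resel_block(fwhm_mm, vs$voxel_size_mm)
  d <- dim(vs$data)

  coarse_pass <- function(offset) {
    cs <- coarse_series(vs, coarse_grid(block, offset))
    if (nrow(cs$series) < 2L) return(array(FALSE, d[1:3]))
    g <- significant_pairs(cs$series, alpha = alpha, correction = correction,
                           min_connections = min_connections, method = method,
                           coords_mm = cs$centroid_mm, baseline = baseline)
    keep <- array(FALSE, d[1:3])
    keep[which(vs$mask)] <- cs$block_id[which(vs$mask)] %in% g$nodes
    keep
  }
  off1 <- pmin(1L, block - 1L)  # degenerate 1-voxel blocks cannot shift
  union_mask <- coarse_pass(c(0L, 0L, 0L)) | coarse_pass(off1)

  out <- list(mask = array(FALSE, d[1:3]), fine_graph = NULL,
              fine_ijk = NULL, coarse_union = union_mask,
              fwhm_mm = as.numeric(fwhm_mm), block = block)
  if (sum(union_mask) < 2L) return(out)

  fine_ijk <- mask_coords(union_mask)
  flat <- matrix(vs$data, prod(d[1:3]), d[4])
  fg <- significant_pairs(flat[which(union_mask), , drop = FALSE],
                          alpha = alpha, correction = correction,
                          min_connections = 1L, method = method,
                          coords_mm = voxel_to_mm(fine_ijk, vs$voxel_size_mm),
                          baseline = baseline)
  sel <- array(FALSE, d[1:3])
  sel[which(union_mask)[fg$nodes]] <- TRUE
  out$mask <- sel
  out$fine_graph <- fg
  out$fine_ijk <- fine_ijk
  out
}

#' Write a pair graph as a TSV edge list
#'
#' Columns: 0-based voxel coordinates of both endpoints, correlation and
#' corrected p-value.
#'
#' @param graph a `pair_graph` from [significant_pairs()].
#' @param ijk voxel index matrix (1-based) that the graph nodes refer to.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_edges_tsv <- function(graph, ijk, path) {
  e <- graph$edges
  df <- data.frame(i_x = ijk[e[, 1], 1] - 1L, i_y = ijk[e[, 1], 2] - 1L,
                   i_z = ijk[e[, 1], 3] - 1L,
                   j_x = ijk[e[, 2], 1] - 1L, j_y = ijk[e[, 2], 2] - 1L,
                   j_z = ijk[e[, 2], 3] - 1L,
                   r = graph$r, p_adjusted = graph$p_adj)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
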
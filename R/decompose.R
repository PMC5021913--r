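# Functional feature space: SVD of the selected-voxel time series, with
# standardised voxel loadings as functional coordinates, and information
# theoretic (MDL / AIC) selection of the number of components.

#' SVD functional features
#'
#' Singular value decomposition of the temporally mean-centred voxel-by-time
#' matrix. The per-voxel loadings on the top `n_components` factors are
#' standardised column-wise to zero mean and unit variance; these
#' standardised weights, together with the spatial coordinates, form the
#' feature space of the spatiofunctional clustering.
#'
#' @param series n x T matrix of voxel time series.
#' @param coords_mm n x 3 matrix of voxel world coordinates (mm).
#' @param n_components number of components P to retain.
#' @return object of class `"functional_features"`: list with
#'   `coords_mm`, `weights` (n x P standardised loadings),
#'   `component_series` (T x P right singular vectors),
#'   `variance_explained` (fraction per retained component), `singular_values`.
#' @examples
#' s <- matrix(rnorm(50 * 30), 50, 30)
#' f <- svd_features(s, matrix(0, 50, 3), 3)
#' round(colMeans(f$weights), 10)  # all zero
#' @export
svd_features <- function(series, coords_mm, n_components) {
  n <- nrow(series)
  n_t <- ncol(series)
  P <- as.integer(n_components)
  if (P < 1L || P > min(n, n_t)) stop("n_components out of range")
  xc <- series - rowMeans(series)
  sv <- svd(xc, nu = P, nv = P)
  if (sum(sv$d > sv$d[1] * 1e-12) < P)
    stop("n_components exceeds the rank of the series matrix")
  w <- sv$u
  sds <- apply(w, 2, stats::sd)
  if (any(sds == 0)) stop("degenerate (constant) component loading")
  w <- scale(w)
  attr(w, "scaled:center") <- attr(w, "scaled:scale") <- NULL
  structure(list(coords_mm = as.matrix(coords_mm), weights = w,
                 component_series = sv$v,
                 variance_explained = (sv$d^2 / sum(sv$d^2))[seq_len(P)],
                 singular_values = sv$d),
            class = "functional_features")
}

#' @export
print.functional_features <- function(x, ...) {
  cat(sprintf("functional_features: %d voxels, %d components (%.1f%% variance)\n",
              nrow(x$weights), ncol(x$weights),
              100 * sum(x$variance_explained)))
  invisible(x)
}

#' Temporal covariance eigenvalues of a voxel-by-time matrix
#'
#' Eigenvalues of the T x T covariance of the mean-centred series, the input
#' expected by [model_order()]; the number of voxels plays the role of the
#' sample count N.
#'
#' @param series n x T matrix.
#' @return decreasing numeric vector of the positive eigenvalues
#'   (numerically null ones, below `max * 1e-12`, are dropped).
#' @export
temporal_eigenvalues <- function(series) {
  xc <- series - rowMeans(series)
  ev <- eigen(crossprod(xc) / (nrow(series) - 1), symmetric = TRUE,
              only.values = TRUE)$values
  ev[ev > max(ev) * 1e-12]
}

#' Information-theoretic model order (number of signal components)
#'
#' The classical eigenvalue-based criterion for the number of sources in
#' white noise: for each candidate order k the log-likelihood term is
#' `-N (p-k) log(g(k)/a(k))` with `g`/`a` the geometric/arithmetic mean of
#' the trailing `p-k` eigenvalues, plus a penalty of
#' `k (2p - k) log(N) / 2` (MDL) or `k (2p - k)` (AIC). The reported order
#' is the argmin, clamped below at 1.
#'
#' @param eigenvalues positive eigenvalues sorted in decreasing order.
#' @param n_samples number of observations N (here: voxels).
#' @param method `"MDL"` or `"AIC"`.
#' @param return_curve if TRUE, attach the criterion curve as an attribute.
#' @return integer order (>= 1), optionally with attribute `"curve"`
#'   (criterion value for k = 0..p-1).
#' @export
model_order <- function(eigenvalues, n_samples, method = c("MDL", "AIC"),
                        return_curve = FALSE) {
  method <- match.arg(method)
  ev <- as.numeric(eigenvalues)
  if (any(ev <= 0)) stop("eigenvalues must be positive")
  if (is.unsorted(rev(ev), strictly = FALSE))
    stop("eigenvalues must be sorted in decreasing order")
  p <- length(ev)
  N <- n_samples
  # suffix means of log-eigenvalues and eigenvalues for k = 0..p-1
  csum_log <- rev(cumsum(rev(log(ev))))
  csum <- rev(cumsum(rev(ev)))
  k <- 0:(p - 1)
  m <- p - k
  loglik <- -N * (csum_log[k + 1] - m * log(csum[k + 1] / m))
  pen <- if (method == "MDL") 0.5 * k * (2 * p - k) * log(N)
         else k * (2 * p - k)
  curve <- loglik + pen
  khat <- max(1L, k[which.min(curve)])
  if (return_curve) attr(khat, "curve") <- curve
  khat
}

#' Pooled per-subject component count
#'
#' Cross-subject pooling rule for the number of functional-kernel
#' components: subject i receives
#' `max(mdl_i, round(mean(median(mdl), median(aic))))` (half-up rounding),
#' which lifts subjects with an overly conservative MDL estimate to the
#' cohort consensus while never reducing a subject's own MDL order.
#'
#' @param per_subject_mdl integer vector of per-subject MDL orders.
#' @param per_subject_aic integer vector of per-subject AIC orders.
#' @param i subject index (default: all subjects).
#' @return integer vector of pooled component counts.
#' @export
pooled_component_count <- function(per_subject_mdl, per_subject_aic,
                                   i = seq_along(per_subject_mdl)) {
  if (length(per_subject_mdl) == 0L) stop("empty cohort")
  if (length(per_subject_mdl) != length(per_subject_aic))
    stop("MDL and AIC vectors must have the same length")
  consensus <- round_half_up(mean(c(stats::median(per_subject_mdl),
                                    stats::median(per_subject_aic))))
  as.integer(pmax(per_subject_mdl[i], consensus))
}

#' Write functional features as TSV
#'
#' @param features a [svd_features()] result.
#' @param path output TSV path (voxel index, coordinates, weights); the
#'   component time courses go to `<path>_components.tsv`.
#' @return invisibly, `path`.
#' @export
write_features_tsv <- function(features, path) {
  w <- features$weights
  colnames(w) <- paste0("w", seq_len(ncol(w)))
  df <- data.frame(voxel = seq_len(nrow(w)),
                   x_mm = features$coords_mm[, 1],
                   y_mm = features$coords_mm[, 2],
                   z_mm = features$coords_mm[, 3], w)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cp <- sub("(\\.tsv)?$", "_components.tsv", path)
  comp <- features$component_series
  colnames(comp) <- paste0("pc", seq_len(ncol(comp)))
  utils::write.table(data.frame(t = seq_len(nrow(comp)), comp), cp,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
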
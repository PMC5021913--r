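# Support Vector Clustering with the spatiofunctional kernel.
#
# The composed kernel k(v_i, v_j) =
#   exp(-sum_k gamma_s_k (dx_k)^2) * exp(-sum_p gamma_F_p (dw_p)^2)
# is a single Gaussian in the space obtained by scaling each spatial axis by
# sqrt(gamma_s_k) and each standardised-weight axis by sqrt(gamma_F_p); all
# internal computations use that scaled embedding.

#' Spatiofunctional kernel parameters
#'
#' @param gamma_spatial positive length-3 vector (mm^-2): inverse squared
#'   spatial bandwidths.
#' @param gamma_functional positive length-P vector: inverse squared
#'   bandwidths for the standardised component weights.
#' @param soft_margin_c box constraint C in (0, 1]; C = 1 is the hard-margin
#'   minimal enclosing sphere.
#' @return object of class `"kernel_params"`.
#' @export
kernel_params <- function(gamma_spatial, gamma_functional,
                          soft_margin_c = 1) {
  stopifnot(length(gamma_spatial) == 3L, all(gamma_spatial > 0),
            length(gamma_functional) >= 1L, all(gamma_functional > 0),
            soft_margin_c > 0, soft_margin_c <= 1)
  structure(list(gamma_spatial = as.numeric(gamma_spatial),
                 gamma_functional = as.numeric(gamma_functional),
                 soft_margin_c = soft_margin_c),
            class = "kernel_params")
}

#' Estimate kernel scale parameters from data properties
#'
#' Spatial scales follow the resel convention
#' `gamma_s_k = 1 / sigma_k^2` with `sigma_k = FWHM_k / 2.35`, so spatial
#' distances are expressed in units of the actual smoothness of the data.
#' Functional scales are `gamma_F_p = 1 / sd_p^2` from the empirical sd of
#' each weight column (equal to 1 after the standardisation contract of
#' [svd_features()], but always re-estimated here).
#'
#' @param fwhm_mm positive length-3 smoothness (mm).
#' @param features a [svd_features()] result, or an n x P weight matrix.
#' @param soft_margin_c box constraint, passed through.
#' @return a [kernel_params()].
#' @examples
#' estimate_gammas(c(4.7, 4.7, 9.4), matrix(rnorm(200), 100, 2))$gamma_spatial
#' # 0.25 0.25 0.0625
#' @export
estimate_gammas <- function(fwhm_mm, features, soft_margin_c = 1) {
  stopifnot(all(fwhm_mm > 0))
  w <- if (inherits(features, "functional_features")) features$weights
       else as.matrix(features)
  sds <- apply(w, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance weight column(s): ",
            paste(which(sds == 0), collapse = ", "))
    sds <- sds[sds > 0]
    if (length(sds) == 0L) stop("no usable weight columns")
  }
  kernel_params(gamma_spatial = 1 / (fwhm_mm / 2.35)^2,
                gamma_functional = 1 / sds^2,
                soft_margin_c = soft_margin_c)
}

# scaled embedding: columns = sqrt(gamma) * (coords | weights)
sf_embed <- function(coords_mm, weights, kp) {
  coords_mm <- as.matrix(coords_mm)
  weights <- as.matrix(weights)
  if (ncol(weights) != length(kp$gamma_functional))
    stop("weight dimension does not match gamma_functional")
  cbind(sweep(coords_mm, 2, sqrt(kp$gamma_spatial), `*`),
        sweep(weights, 2, sqrt(kp$gamma_functional), `*`))
}

# pairwise squared distances between rows of scaled matrices
sq_dist <- function(x, y = x) {
  d2 <- outer(rowSums(x^2), rowSums(y^2), `+`) - 2 * tcrossprod(x, y)
  pmax(d2, 0)
}

#' Spatiofunctional kernel
#'
#' @param v_i,v_j lists with elements `coords_mm` (length 3) and `weights`
#'   (length P), or matrices of such rows.
#' @param kp a [kernel_params()].
#' @return kernel value(s) in (0, 1]; 1 iff the two voxels coincide in both
#'   space and functional weights.
#' @export
sf_kernel <- function(v_i, v_j, kp) {
  xi <- sf_embed(rbind(v_i$coords_mm), rbind(v_i$weights), kp)
  xj <- sf_embed(rbind(v_j$coords_mm), rbind(v_j$weights), kp)
  drop(exp(-sq_dist(xi, xj)))
}

#' Kernel matrix of the spatiofunctional kernel
#'
#' @param coords_mm n x 3 coordinates.
#' @param weights n x P standardised weights.
#' @param kp a [kernel_params()].
#' @return n x n symmetric kernel matrix with unit diagonal.
#' @export
sf_kernel_matrix <- function(coords_mm, weights, kp) {
  x <- sf_embed(coords_mm, weights, kp)
  k <- exp(-sq_dist(x))
  diag(k) <- 1
  k
}

#' Fit the minimal enclosing hypersphere (SVC domain description)
#'
#' Solves the dual problem: maximise
#' `sum_j beta_j K_jj - sum_ij beta_i beta_j K_ij` subject to
#' `sum beta = 1`, `0 <= beta_i <= C`, by deterministic SMO-type pairwise
#' coordinate optimisation (most-violating-pair selection, exact line
#' search). With a Gaussian kernel (unit diagonal) this is the kernel-space
#' minimal enclosing ball; support vectors (`0 < beta < C`) lie on the
#' sphere of squared radius R^2.
#'
#' @param kernel_matrix symmetric PSD matrix with unit diagonal.
#' @param C box constraint in `[1/n, 1]`.
#' @param tol_kkt KKT violation tolerance on the dual gradient.
#' @param max_iter iteration cap.
#' @return object of class `"svc_sphere"`: list with `beta`, `r_squared`,
#'   `support` (indices with `0 < beta < C`), `b_term`
#'   (`sum_ij beta_i beta_j K_ij`), `objective` (dual objective value), `C`.
#' @examples
#' k <- matrix(c(1, 0.5, 0.5, 1), 2)
#' fit_sphere(k)$r_squared  # (1 - 0.5) / 2
#' @export
fit_sphere <- function(kernel_matrix, C = 1, tol_kkt = 1e-9,
                       max_iter = NULL) {
  K <- kernel_matrix
  n <- nrow(K)
  if (n == 0L) stop("empty kernel matrix")
  if (C * n < 1 - 1e-12) stop("infeasible C: need C >= 1/n")
  if (max(abs(K - t(K))) > 1e-8) stop("kernel matrix must be symmetric")
  dK <- diag(K)
  if (n == 1L) {
    return(structure(list(beta = 1, r_squared = 0, support = 1L,
                          b_term = dK[1], objective = 0, C = C),
                     class = "svc_sphere"))
  }
  if (is.null(max_iter)) max_iter <- max(200L * n, 20000L)
  beta <- rep(1 / n, n)
  # dual in min form: f(beta) = beta' K beta - sum beta_i K_ii
  g <- 2 * drop(K %*% beta) - dK
  eps_b <- 1e-12
  for (it in seq_len(max_iter)) {
    up <- beta < C - eps_b
    dn <- beta > eps_b
    i <- which(up)[which.min(g[up])]
    j <- which(dn)[which.max(g[dn])]
    gap <- g[j] - g[i]
    if (gap < tol_kkt) break
    denom <- 2 * (K[i, i] + K[j, j] - 2 * K[i, j])
    t_step <- if (denom > 1e-15) gap / denom else Inf
    t_step <- min(t_step, beta[j], C - beta[i])
    beta[i] <- beta[i] + t_step
    beta[j] <- beta[j] - t_step
    g <- g + 2 * t_step * (K[, i] - K[, j])
  }
  b_term <- drop(crossprod(beta, K %*% beta))
  objective <- sum(beta * dK) - b_term
  # R^2(x_i) = K_ii - 2 (K beta)_i + b_term; support vectors are strictly
  # inside the box
  r2_all <- dK - (g + dK - 2 * b_term) - b_term  # = dK - 2(K beta)_i + b
  sv_tol <- 1e-7
  support <- which(beta > sv_tol & beta < C - sv_tol)
  if (length(support) == 0L) support <- which(beta > sv_tol)
  r_squared <- max(0, mean(r2_all[support]))
  structure(list(beta = beta, r_squared = r_squared, support = support,
                 b_term = b_term, objective = objective, C = C,
                 r2_train = r2_all, iterations = it),
            class = "svc_sphere")
}

#' @export
print.svc_sphere <- function(x, ...) {
  cat(sprintf("svc_sphere: n = %d, R^2 = %.6g, %d support vectors (C = %g)\n",
              length(x$beta), x$r_squared, length(x$support), x$C))
  invisible(x)
}

#' Squared kernel-space distance to the sphere centre
#'
#' Evaluates `R^2(x) = K(x,x) - 2 sum_j beta_j K(x_j, x) +
#' sum_ij beta_i beta_j K(x_i, x_j)` for query points; the double sum is
#' reused from the fit.
#'
#' @param model an `"svc_sphere"` fit.
#' @param kvec kernel values between the query point(s) and the training
#'   points: a length-n vector or an n x q matrix.
#' @param k_self kernel self-similarity of the query (1 for Gaussian
#'   kernels).
#' @return squared distance(s) from the sphere centre.
#' @export
radius_sq <- function(model, kvec, k_self = 1) {
  kvec <- as.matrix(kvec)
  drop(k_self - 2 * crossprod(kvec, model$beta) + model$b_term)
}

# R^2 at arbitrary points in the scaled embedding (rows of y_scaled),
# given training embedding rows x_scaled. Only points with nonzero beta
# contribute to the kernel sum.
radius_sq_embedded <- function(model, x_scaled, y_scaled) {
  nz <- which(model$beta > 1e-10)
  kv <- exp(-sq_dist(x_scaled[nz, , drop = FALSE], y_scaled))
  drop(1 - 2 * crossprod(kv, model$beta[nz]) + model$b_term)
}

# numeric tolerance for "inside the sphere"
inside_tol <- function(r_squared) 1e-6 * r_squared + 1e-12

#' Path-sampling adjacency matrix
#'
#' Two points are adjacent iff every one of `n_samples` equispaced interior
#' points on the straight segment between them (in the joint
#' coordinate/weight input space) lies inside the fitted sphere,
#' i.e. `R^2(y) <= R^2 + tol`.
#'
#' @param coords_mm n x 3 coordinates of the fitted points.
#' @param weights n x P standardised weights.
#' @param kp the [kernel_params()] used for the fit.
#' @param model the fitted `"svc_sphere"`.
#' @param n_samples interior sample points per segment (default 20).
#' @return n x n logical adjacency matrix (diagonal TRUE).
#' @export
path_adjacency <- function(coords_mm, weights, kp, model, n_samples = 20L) {
  x <- sf_embed(coords_mm, weights, kp)
  n <- nrow(x)
  A <- diag(n) > 0
  if (n < 2L) return(A)
  pairs <- which(upper.tri(A), arr.ind = TRUE)
  conn <- path_pairs_connected(x, model, pairs, n_samples)
  A[pairs] <- conn
  A[pairs[, c(2, 1), drop = FALSE]] <- conn
  A
}

# batched evaluation of the segment test for a set of index pairs; sample
# points are visited middle-out so that pairs whose path leaves the sphere
# (typically near the segment midpoint) drop out after one or two samples
path_pairs_connected <- function(x_scaled, model, pairs, n_samples,
                                 chunk = 2048L) {
  thr <- model$r_squared + inside_tol(model$r_squared)
  ts <- seq_len(n_samples) / (n_samples + 1)
  ts <- ts[order(abs(ts - 0.5))]
  m <- nrow(pairs)
  out <- logical(m)
  for (s in seq(1L, m, by = chunk)) {
    idx <- s:min(s + chunk - 1L, m)
    a <- x_scaled[pairs[idx, 1], , drop = FALSE]
    b <- x_scaled[pairs[idx, 2], , drop = FALSE]
    alive <- seq_along(idx)
    for (t in ts) {
      y <- a[alive, , drop = FALSE] +
        t * (b[alive, , drop = FALSE] - a[alive, , drop = FALSE])
      r2 <- radius_sq_embedded(model, x_scaled, y)
      alive <- alive[r2 <= thr]
      if (length(alive) == 0L) break
    }
    out[idx[alive]] <- TRUE
  }
  out
}

# Connected components of the path adjacency, computed without testing
# pairs whose endpoints are already connected through earlier edges (the
# skipped tests cannot change the components). Pairs are visited in order
# of increasing embedded distance so that dense regions coalesce early.
svc_components <- function(x_scaled, model, n_samples = 20L) {
  n <- nrow(x_scaled)
  if (n == 1L) return(1L)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  d2 <- rowSums((x_scaled[pairs[, 1], , drop = FALSE] -
                   x_scaled[pairs[, 2], , drop = FALSE])^2)
  ord <- order(d2)
  pairs <- pairs[ord, , drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ptr <- 1L
  m <- nrow(pairs)
  chunk <- 512L
  while (ptr <= m) {
    take_i <- integer(0)
    take_j <- integer(0)
    while (ptr <= m && length(take_i) < chunk) {
      ri <- find(pairs[ptr, 1])
      rj <- find(pairs[ptr, 2])
      if (ri != rj) {
        take_i <- c(take_i, pairs[ptr, 1])
        take_j <- c(take_j, pairs[ptr, 2])
      }
      ptr <- ptr + 1L
    }
    if (length(take_i) == 0L) next
    conn <- path_pairs_connected(x_scaled, model,
                                 cbind(take_i, take_j), n_samples)
    for (q in which(conn)) {
      ri <- find(take_i[q])
      rj <- find(take_j[q])
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Support Vector Clustering of voxels
#'
#' Fits the minimal enclosing hypersphere in the spatiofunctional kernel
#' space and labels clusters as the connected components of the
#' path-sampling adjacency graph. When a parcellation is supplied, the
#' sphere fit and the segmentation run independently inside each parcel
#' (giving the clustering more compact spatial domains); ROI ids are
#' globally unique either way.
#'
#' @param features a [svd_features()] result.
#' @param kp a [kernel_params()]; `NULL` estimates it with
#'   [estimate_gammas()] from `fwhm_mm`.
#' @param parcellation optional integer vector (length n) of parcel labels
#'   per voxel, or `NULL` for a single domain.
#' @param fwhm_mm smoothness used when `kp` is `NULL`.
#' @param n_path_samples interior samples for the segment test.
#' @param series optional n x T matrix of the voxels' time series, used to
#'   attach per-ROI mean time courses.
#' @param min_cluster_size clusters smaller than this are still reported
#'   (every voxel keeps exactly one label); kept for the ROI table only.
#' @return object of class `"snc_clusters"`: list with `labels` (length n),
#'   `roi_table` (data.frame: roi_id, n_voxels, centroid, parcel),
#'   `roi_mean_series` (m x T or NULL), `spheres` (per-parcel fits), `kp`.
#' @export
svc_cluster <- function(features, kp = NULL, parcellation = NULL,
                        fwhm_mm = NULL, n_path_samples = 20L,
                        series = NULL, min_cluster_size = 1L) {
  stopifnot(inherits(features, "functional_features"))
  n <- nrow(features$weights)
  if (n == 0L) stop("no voxels to cluster")
  if (is.null(kp)) {
    if (is.null(fwhm_mm)) stop("either `kp` or `fwhm_mm` must be given")
    kp <- estimate_gammas(fwhm_mm, features)
  }
  parcel <- if (is.null(parcellation)) rep(1L, n) else as.integer(parcellation)
  if (length(parcel) != n) stop("parcellation length mismatch")
  x <- sf_embed(features$coords_mm, features$weights, kp)
  labels <- integer(n)
  spheres <- list()
  next_id <- 0L
  for (p in sort(unique(parcel))) {
    idx <- which(parcel == p)
    if (length(idx) == 1L) {
      labels[idx] <- next_id + 1L
      next_id <- next_id + 1L
      next
    }
    xk <- x[idx, , drop = FALSE]
    K <- exp(-sq_dist(xk))
    diag(K) <- 1
    mod <- fit_sphere(K, C = kp$soft_margin_c)
    comp <- svc_components(xk, mod, n_samples = n_path_samples)
    labels[idx] <- next_id + comp
    next_id <- next_id + max(comp)
    spheres[[as.character(p)]] <- mod
  }
  sizes <- tabulate(labels)
  cent <- rowsum(features$coords_mm, labels) / sizes
  roi_table <- data.frame(roi_id = seq_along(sizes), n_voxels = sizes,
                          x_mm = cent[, 1], y_mm = cent[, 2],
                          z_mm = cent[, 3],
                          parcel = as.integer(rowsum(parcel, labels) / sizes))
  roi_mean <- NULL
  if (!is.null(series)) {
    roi_mean <- rowsum(series - rowMeans(series), labels) / sizes
  }
  structure(list(labels = labels, roi_table = roi_table,
                 roi_mean_series = roi_mean, spheres = spheres, kp = kp,
                 min_cluster_size = min_cluster_size),
            class = "snc_clusters")
}

#' @export
print.snc_clusters <- function(x, ...) {
  cat(sprintf("snc_clusters: %d voxels in %d ROIs (largest %d voxels)\n",
              length(x$labels), nrow(x$roi_table), max(x$roi_table$n_voxels)))
  invisible(x)
}
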
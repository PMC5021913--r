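test_that("spatiofunctional kernel: identity, symmetry, direct evaluation", {
  kp <- kernel_params(c(0.25, 0.25, 0.25), c(1, 1))
  v1 <- list(coords_mm = c(1, 2, 3), weights = c(0.5, -0.5))
  v2 <- list(coords_mm = c(3, 2, 3), weights = c(0.5, -0.5))
  expect_equal(sf_kernel(v1, v1, kp), 1)
  expect_equal(sf_kernel(v1, v2, kp), sf_kernel(v2, v1, kp))
  # FWHM 4.7 mm -> sigma 2 mm -> gamma 0.25; dx = 2 mm -> exp(-1)
  expect_equal(sf_kernel(v1, v2, kp), exp(-1), tolerance = 1e-12)

  v3 <- list(coords_mm = c(1, 2, 3), weights = c(1.5, -0.5))
  expect_equal(sf_kernel(v1, v3, kp), exp(-1), tolerance = 1e-12)
  expect_error(sf_kernel(v1, list(coords_mm = c(0, 0, 0), weights = 1), kp),
               "dimension")
})

test_that("gamma estimators follow the resel and loading-sd conventions", {
  w <- matrix(rnorm(300), 100)
  kp <- estimate_gammas(c(2.35, 2.35, 2.35), w)
  expect_equal(kp$gamma_spatial, c(1, 1, 1))
  kp2 <- estimate_gammas(c(4.7, 4.7, 9.4), w)
  expect_equal(kp2$gamma_spatial, c(0.25, 0.25, 0.0625))
  expect_equal(kp2$gamma_functional, 1 / apply(w, 2, sd)^2)

  ws <- scale(w)
  expect_equal(estimate_gammas(c(4.7, 4.7, 4.7), ws)$gamma_functional,
               rep(1, 3), tolerance = 1e-12)

  w0 <- cbind(w[, 1], 0)
  expect_warning(kp3 <- estimate_gammas(c(4.7, 4.7, 4.7), w0),
                 "zero-variance")
  expect_length(kp3$gamma_functional, 1)
})

test_that("fit_sphere handles the single- and two-point closed forms", {
  expect_equal(fit_sphere(matrix(1, 1, 1))$r_squared, 0)
  expect_equal(fit_sphere(matrix(1, 1, 1))$beta, 1)
  for (k in c(0.05, 0.3, 0.7, 0.95)) {
    m <- fit_sphere(matrix(c(1, k, k, 1), 2))
    expect_equal(m$beta, c(0.5, 0.5), tolerance = 1e-9)
    expect_equal(m$r_squared, (1 - k) / 2, tolerance = 1e-9)
  }
  expect_error(fit_sphere(matrix(c(1, 0.5, 0.5, 1), 2), C = 0.3),
               "infeasible")
  expect_error(fit_sphere(matrix(c(1, 0.7, 0.2, 1), 2)), "symmetric")
})

test_that("dual feasibility invariants hold on random fits", {
  set.seed(8)
  for (i in 1:10) {
    n <- sample(3:25, 1)
    C <- sample(c(1, 0.5, 2 / n), 1)
    x <- matrix(rnorm(n * 4), n)
    K <- exp(-as.matrix(dist(x))^2 / 4)
    diag(K) <- 1
    m <- fit_sphere(K, C = C)
    expect_equal(sum(m$beta), 1, tolerance = 1e-9)
    expect_true(all(m$beta >= -1e-12 & m$beta <= C + 1e-12))
    tol <- 1e-6 * m$r_squared + 1e-6
    # interior points (beta < C) lie inside or on the sphere; bounded
    # support vectors (beta = C) may sit outside it. Free support vectors
    # lie on the surface.
    interior <- m$beta < C - 1e-8
    expect_true(all(m$r2_train[interior] <= m$r_squared + tol))
    expect_true(all(abs(m$r2_train[m$support] - m$r_squared) <= tol))
  }
})

test_that("radius_sq evaluates the sphere distance function", {
  expect_equal(radius_sq(fit_sphere(matrix(1, 1, 1)), 1), 0)
  k12 <- 0.4
  m <- fit_sphere(matrix(c(1, k12, k12, 1), 2))
  # at a support vector
  expect_equal(radius_sq(m, c(1, k12)), (1 - k12) / 2, tolerance = 1e-9)
  # far from all training points the distance tends to 1 + b_term
  expect_equal(radius_sq(m, c(0, 0)), 1 + m$b_term, tolerance = 1e-12)
})

test_that("path adjacency separates blobs and matches dense refinement", {
  f <- two_blob_features(seed = 9)
  kp <- kernel_params(c(0.25, 0.25, 0.25), 1)
  K <- sf_kernel_matrix(f$coords_mm, f$weights, kp)
  m <- fit_sphere(K)
  A20 <- path_adjacency(f$coords_mm, f$weights, kp, m, n_samples = 20L)
  expect_true(isSymmetric(A20))
  expect_true(all(diag(A20)))
  blob <- rep(1:2, each = 8)
  expect_true(all(A20[blob == 1, blob == 2] == FALSE))
  expect_equal(max(adjacency_components(A20)), 2)

  # sampling sufficiency: 20 samples agree with 200 on small instances
  A200 <- path_adjacency(f$coords_mm, f$weights, kp, m, n_samples = 200L)
  expect_identical(A20, A200)

  # coincident points are always adjacent
  f2 <- f; f2$coords_mm[2, ] <- f2$coords_mm[1, ]
  f2$weights[2, ] <- f2$weights[1, ]
  K2 <- sf_kernel_matrix(f2$coords_mm, f2$weights, kp)
  m2 <- fit_sphere(K2)
  A2 <- path_adjacency(f2$coords_mm, f2$weights, kp, m2)
  expect_true(A2[1, 2])
})

test_that("svc_cluster groups blobs, labels every voxel, honours parcels", {
  f <- two_blob_features(seed = 10)
  kp <- kernel_params(c(0.25, 0.25, 0.25), 1)
  cl <- svc_cluster(f, kp = kp)
  expect_equal(nrow(cl$roi_table), 2)
  expect_length(cl$labels, 16)
  expect_true(all(cl$labels %in% cl$roi_table$roi_id))
  blob <- rep(1:2, each = 8)
  expect_equal(length(unique(cl$labels[blob == 1])), 1)
  expect_equal(length(unique(cl$labels[blob == 2])), 1)

  # identical features -> a single cluster
  fid <- f
  fid$coords_mm <- matrix(1, 16, 3)
  fid$weights <- matrix(0.3, 16, 1)
  expect_equal(nrow(svc_cluster(fid, kp = kp)$roi_table), 1)

  # parcellation: clusters are formed within parcels; a singleton parcel
  # becomes a singleton ROI
  parcel <- c(rep(1L, 8), rep(2L, 7), 3L)
  clp <- svc_cluster(f, kp = kp, parcellation = parcel)
  expect_equal(nrow(clp$roi_table), 3)
  expect_equal(sum(clp$labels == clp$labels[16]), 1)
})

test_that("pipeline agrees with a brute-force reference on small instances", {
  kp <- kernel_params(c(0.25, 0.25, 0.25), 1)
  for (s in 1:4) {
    set.seed(100 + s)
    n <- sample(8:20, 1)
    coords <- matrix(rnorm(n * 3, sd = 3), n)
    coords[seq_len(n %/% 2), 1] <- coords[seq_len(n %/% 2), 1] + 15
    w <- matrix(rnorm(n, sd = 0.5), ncol = 1)
    ref <- brute_svc_reference(coords, w, kp)
    K <- sf_kernel_matrix(coords, w, kp)
    m <- fit_sphere(K)
    expect_equal(m$r_squared, ref$r_squared, tolerance = 1e-5)
    f <- structure(list(coords_mm = coords, weights = w,
                        component_series = matrix(0, 5, 1),
                        variance_explained = 1),
                   class = "functional_features")
    cl <- svc_cluster(f, kp = kp)
    # identical partitions (labels may be permuted)
    expect_equal(fowlkes_mallows(cl$labels, ref$labels), 1)
  }
})

test_that("svc_components equals components of the full path adjacency", {
  f <- two_blob_features(n1 = 6, n2 = 6, seed = 12)
  kp <- kernel_params(c(0.2, 0.2, 0.2), 1)
  x <- snclust:::sf_embed(f$coords_mm, f$weights, kp)
  K <- exp(-snclust:::sq_dist(x)); diag(K) <- 1
  m <- fit_sphere(K)
  A <- path_adjacency(f$coords_mm, f$weights, kp, m)
  lab_full <- adjacency_components(A)
  lab_fast <- snclust:::svc_components(x, m)
  expect_equal(fowlkes_mallows(lab_fast, lab_full), 1)
})
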
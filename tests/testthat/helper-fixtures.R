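# Shared fixtures: all synthetic, built in code at test time.

# tiny 4D white-noise volume
tiny_noise_vs <- function(shape = c(8L, 8L, 4L), n_t = 30L, seed = 1,
                          voxel = c(3, 3, 3)) {
  set.seed(seed)
  volume_series(array(rnorm(prod(shape) * n_t), c(shape, n_t)),
                voxel_size_mm = voxel)
}

# two well-separated blobs in feature space: n1 + n2 points, 3 spatial dims
# + 1 functional weight; within-blob spread `spread`, centres `gap_mm` apart
two_blob_features <- function(n1 = 8L, n2 = 8L, gap_mm = 40, spread = 0.8,
                              seed = 1) {
  set.seed(seed)
  coords <- rbind(matrix(rnorm(n1 * 3, 0, spread), n1),
                  cbind(rnorm(n2, gap_mm, spread), rnorm(n2, 0, spread),
                        rnorm(n2, 0, spread)))
  w <- matrix(c(rnorm(n1, -1, 0.05), rnorm(n2, 1, 0.05)), ncol = 1)
  structure(list(coords_mm = coords, weights = w,
                 component_series = matrix(0, 10, 1),
                 variance_explained = 1, singular_values = 1),
            class = "functional_features")
}

# independent cluster-component labelling via igraph, used as the reference
# for the union-find component path in svc_cluster
adjacency_components <- function(A) {
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  igraph::components(g)$membership
}

# exhaustive maximal-clique oracle: all subsets of an m <= 12 vertex graph
brute_max_clique_with_seed <- function(adj, seed_v) {
  m <- nrow(adj)
  best <- integer(0)
  for (code in seq_len(2^m) - 1L) {
    v <- which(bitwAnd(code, 2^(seq_len(m) - 1L)) > 0L)
    if (!(seed_v %in% v)) next
    if (length(v) >= 2L) {
      sub <- adj[v, v, drop = FALSE]
      if (any(sub[upper.tri(sub)] == 0)) next
    }
    # maximal: no vertex outside v connected to all of v
    out <- setdiff(seq_len(m), v)
    if (length(out) > 0L &&
        any(vapply(out, function(u) all(adj[u, v] == 1), logical(1))))
      next
    if (length(v) > length(best) ||
        (length(v) == length(best) &&
           paste(sprintf("%09d", v), collapse = ",") <
             paste(sprintf("%09d", best), collapse = ",")))
      best <- v
  }
  best
}

# dense reference for the SVC pipeline on small instances: full kernel,
# sphere via a fine projected-gradient descent (independent of the SMO),
# dense 200-sample path adjacency, igraph components
brute_svc_reference <- function(coords, weights, kp, n_samples = 200L) {
  K <- sf_kernel_matrix(coords, weights, kp)
  n <- nrow(K)
  # projected gradient on the simplex (independent solver)
  beta <- rep(1 / n, n)
  for (it in 1:20000) {
    g <- 2 * drop(K %*% beta)
    step <- 1 / (2 * n)
    beta_new <- beta - step * g
    # project onto {sum = 1, beta >= 0} (Euclidean projection)
    u <- sort(beta_new, decreasing = TRUE)
    css <- cumsum(u)
    rho <- max(which(u + (1 - css) / seq_len(n) > 0))
    theta <- (1 - css[rho]) / rho
    beta_new <- pmax(beta_new + theta, 0)
    if (max(abs(beta_new - beta)) < 1e-12) { beta <- beta_new; break }
    beta <- beta_new
  }
  b <- drop(crossprod(beta, K %*% beta))
  r2_all <- 1 - 2 * drop(K %*% beta) + b
  r2 <- max(r2_all[beta > 1e-7])
  x <- snclust:::sf_embed(coords, weights, kp)
  A <- diag(n) > 0
  ts <- seq_len(n_samples) / (n_samples + 1)
  thr <- r2 + 1e-6 * r2 + 1e-12
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- TRUE
    for (t in ts) {
      y <- x[i, ] + t * (x[j, ] - x[i, ])
      kv <- exp(-colSums((t(x) - y)^2))
      if (1 - 2 * sum(beta * kv) + b > thr) { ok <- FALSE; break }
    }
    A[i, j] <- A[j, i] <- ok
  }
  list(beta = beta, r_squared = r2, adjacency = A,
       labels = adjacency_components(A))
}
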
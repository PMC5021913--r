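test_that("estimate_fwhm recovers white-noise and smoothed smoothness", {
  vs <- tiny_noise_vs(c(20L, 20L, 8L), n_t = 60L, seed = 3)
  fw <- estimate_fwhm(vs)
  # white noise: lambda = 2, FWHM = sqrt(2 ln 2) = 1.18 voxels
  expect_true(all(abs(attr(fw, "fwhm_vox") - sqrt(2 * log(2))) < 0.08))

  set.seed(4)
  arr <- array(rnorm(24 * 24 * 12 * 40), c(24, 24, 12, 40))
  arr <- snclust:::smooth_gaussian_4d(arr, c(2, 2, 2))
  vs2 <- volume_series(arr, c(1, 1, 1))
  fw2 <- estimate_fwhm(vs2)
  # sigma = 2 voxels -> FWHM = 4.71 voxels, recovered within 15%
  expect_true(all(abs(fw2 - 2 * sqrt(8 * log(2))) / (2 * sqrt(8 * log(2)))
                  < 0.15))
})

test_that("estimate_fwhm degenerate inputs take the error/warning paths", {
  vs <- tiny_noise_vs(c(6L, 6L, 2L), n_t = 20L)
  vs$data[] <- 1  # constant image
  expect_error(suppressWarnings(estimate_fwhm(vs)), "no variable")

  # single-slice input: z axis has no neighbour pairs
  h <- volume_series(array(rnorm(6 * 6 * 1 * 20), c(6, 6, 1, 20)), c(3, 3, 6))
  expect_warning(fw <- estimate_fwhm(h), "axis 3")
  expect_equal(attr(fw, "fwhm_vox")[3], 1)
})

test_that("coarse_series averages in-mask voxels per block", {
  # uniform field: every coarse series equals the constant series
  d <- c(4L, 4L, 2L)
  arr <- array(rep(seq_len(6), each = prod(d)), c(d, 6))
  vs <- volume_series(arr, c(2, 2, 2))
  cs <- coarse_series(vs, coarse_grid(c(2L, 2L, 2L)))
  expect_equal(nrow(cs$series), 4)
  for (i in 1:4) expect_equal(unname(cs$series[i, ]), as.numeric(1:6))

  # hand-built 4 x 4 x 1 volume, 2 x 2 x 1 blocks: block means by hand
  arr2 <- array(0, c(4, 4, 1, 2))
  arr2[, , 1, 1] <- matrix(1:16, 4, 4)
  arr2[, , 1, 2] <- matrix(1:16, 4, 4) * 2
  vs2 <- volume_series(arr2, c(3, 3, 3))
  cs2 <- coarse_series(vs2, coarse_grid(c(2L, 2L, 1L)))
  expect_equal(nrow(cs2$series), 4)
  m <- matrix(1:16, 4, 4)
  hand <- c(mean(m[1:2, 1:2]), mean(m[3:4, 1:2]),
            mean(m[1:2, 3:4]), mean(m[3:4, 3:4]))
  expect_equal(unname(sort(cs2$series[, 1])), sort(hand))
  expect_equal(unname(cs2$series[, 2]), unname(cs2$series[, 1] * 2))

  # a block with a single in-mask voxel reproduces that voxel's series
  mask <- array(FALSE, c(4, 4, 1))
  mask[1, 1, 1] <- TRUE
  mask[3:4, 3:4, 1] <- TRUE
  vs3 <- volume_series(arr2, c(3, 3, 3), mask = mask)
  cs3 <- coarse_series(vs3, coarse_grid(c(2L, 2L, 1L)))
  expect_equal(nrow(cs3$series), 2)
  expect_true(any(apply(cs3$series, 1, function(s)
    isTRUE(all.equal(unname(s), c(arr2[1, 1, 1, 1], arr2[1, 1, 1, 2]))))))

  expect_error(coarse_series(volume_series(arr2, c(3, 3, 3),
                                           mask = array(FALSE, c(4, 4, 1))),
                             coarse_grid(c(2L, 2L, 1L))), "empty mask")
})

test_that("significant_pairs finds planted correlation and controls type I", {
  set.seed(11)
  n_t <- 60
  base <- rnorm(n_t)
  series <- rbind(base, base + rnorm(n_t, sd = 1e-3),
                  matrix(rnorm(8 * n_t), 8))
  g <- significant_pairs(series, alpha = 0.05, min_connections = 1L)
  expect_true(any(g$edges[, 1] == 1 & g$edges[, 2] == 2))

  # family-wise control: 100 independent series, many repetitions
  set.seed(12)
  fw_hits <- vapply(1:40, function(i) {
    s <- matrix(rnorm(100 * 30), 100)
    nrow(significant_pairs(s, alpha = 0.05, min_connections = 1L)$edges) > 0
  }, logical(1))
  expect_lt(mean(fw_hits), 0.05 + 3 * sqrt(0.05 * 0.95 / 40))
})

test_that("significant_pairs validates input and prunes by degree", {
  s <- matrix(rnorm(5 * 30), 5)
  expect_error(significant_pairs(s, alpha = 1.2), "alpha")
  s[3, ] <- 7
  expect_warning(significant_pairs(s), "zero-variance")

  # degree pruning: a hub correlated with 4 others survives
  # min_connections = 4, the satellites (degree 1) do not
  set.seed(13)
  hub <- rnorm(80)
  sats <- t(sapply(1:4, function(i) hub + rnorm(80, sd = 0.2)))
  noise <- matrix(rnorm(10 * 80), 10)
  g4 <- significant_pairs(rbind(hub, sats, noise), min_connections = 4L)
  expect_true(1 %in% g4$nodes)
  # satellites correlate with the hub and each other -> degree 4 each; add
  # a lone pair to check removal
  lone <- rnorm(80)
  g2 <- significant_pairs(rbind(lone, lone + rnorm(80, sd = 0.1), noise),
                          min_connections = 4L)
  expect_false(1 %in% g2$nodes)
})

test_that("distance baseline removes smoothing-induced neighbour edges", {
  set.seed(14)
  arr <- array(rnorm(16 * 16 * 1 * 50), c(16, 16, 1, 50))
  arr <- snclust:::smooth_gaussian_4d(arr, c(1, 1, 0))  # heavy 2D smoothing
  vs <- volume_series(arr, c(3, 3, 3))
  ms <- mask_series(vs)
  plain <- significant_pairs(ms$series, min_connections = 1L)
  corrected <- significant_pairs(ms$series, min_connections = 1L,
                                 coords_mm = ms$coords_mm,
                                 baseline = "distance")
  expect_gt(nrow(plain$edges), 50)       # smoothing floods the plain test
  expect_lt(nrow(corrected$edges), nrow(plain$edges) / 10)
})

test_that("select_voxels keeps ROI voxels, drops background, respects mask", {
  ph <- default_network_phantom(seed = 5)
  sel <- select_voxels(ph$vs, fwhm_mm = estimate_fwhm(ph$vs))
  expect_true(all(!sel$mask | ph$vs$mask))      # output within input mask
  retention <- sum(sel$mask & ph$truth > 0) / sum(ph$truth > 0)
  bg_rate <- sum(sel$mask & ph$truth == 0) / sum(ph$truth == 0)
  expect_gte(retention, 0.9)
  expect_lt(bg_rate, 0.5)
  # fine pass operated only inside the coarse union
  expect_true(all(!sel$mask | sel$coarse_union))
})

test_that("pure-noise volume yields an empty or near-empty selection", {
  vs <- tiny_noise_vs(c(12L, 12L, 6L), n_t = 60L, seed = 21)
  sel <- select_voxels(vs, fwhm_mm = c(3, 3, 3))
  expect_lt(sum(sel$mask), 0.01 * sum(vs$mask) + 3)
})

test_that("lowering alpha never adds edges within a fixed test family", {
  # strict nesting holds per significance pass (the end-to-end selection is
  # only approximately nested because the fine-scale Bonferroni family
  # shrinks with the coarse union)
  set.seed(16)
  s <- matrix(rnorm(30 * 50), 30)
  s[1:6, ] <- s[1:6, ] + outer(rep(1.2, 6), rnorm(50))
  key <- function(g) paste(g$edges[, 1], g$edges[, 2])
  e05 <- key(significant_pairs(s, alpha = 0.05))
  e01 <- key(significant_pairs(s, alpha = 0.01))
  e001 <- key(significant_pairs(s, alpha = 0.001))
  expect_true(all(e01 %in% e05))
  expect_true(all(e001 %in% e01))
})

test_that("the shifted grid recovers voxels straddling a block boundary", {
  # an ROI placed across the offset-0 block boundary: the two halves fall
  # into different resel blocks whose means dilute the signal; the shifted
  # grid realigns a block onto the ROI
  set.seed(31)
  shape <- c(12L, 12L, 4L)
  n_t <- 80L
  src <- rnorm(n_t)
  arr <- array(rnorm(prod(shape) * n_t, sd = 1), c(shape, n_t))
  roi <- as.matrix(expand.grid(4:5, 4:5, 2))  # straddles 2-voxel grid at x=4|5
  roi2 <- as.matrix(expand.grid(8:9, 8:9, 3))
  for (v in seq_len(nrow(roi)))
    arr[roi[v, 1], roi[v, 2], roi[v, 3], ] <-
      arr[roi[v, 1], roi[v, 2], roi[v, 3], ] + 2 * src
  for (v in seq_len(nrow(roi2)))
    arr[roi2[v, 1], roi2[v, 2], roi2[v, 3], ] <-
      arr[roi2[v, 1], roi2[v, 2], roi2[v, 3], ] + 2 * src
  vs <- volume_series(arr, c(3, 3, 3))
  sel <- select_voxels(vs, fwhm_mm = c(6, 6, 6), min_connections = 1L)
  hits <- sum(sel$mask[rbind(roi, roi2)])
  expect_gte(hits, 7)
  # two-pass union is order independent: recompute and compare
  sel_b <- select_voxels(vs, fwhm_mm = c(6, 6, 6), min_connections = 1L)
  expect_identical(sel$mask, sel_b$mask)
})
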
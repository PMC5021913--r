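test_that("block regressor reproduces the canonical design and edge cases", {
  d <- block_design(30, 15, 6, 2.5, 285)
  r <- block_regressor(d)
  expect_length(r, 114)
  runs <- rle(r)
  expect_equal(sum(runs$values == 1), 6)
  expect_true(all(runs$lengths[runs$values == 1] == 12))

  expect_identical(block_regressor(block_design(5, 5, 0 + 0, 1, 20)),
                   integer(20))

  expect_equal(block_regressor(block_design(5, 5, 2, 1, 20)),
               rep(c(1L, 0L, 1L, 0L), each = 5))
})

test_that("random block order is seeded and never merges ON periods", {
  d <- block_design(30, 15, 6, 2.5, 285 * 2)  # slack so all layouts fit
  for (s in 1:5) {
    r <- block_regressor(d, order = "random", seed = s)
    runs <- rle(r)
    expect_equal(sum(runs$values == 1), 6)
  }
  expect_identical(block_regressor(d, order = "random", seed = 3),
                   block_regressor(d, order = "random", seed = 3))
})

test_that("strict TR ratio handling rejects non-integral blocks", {
  d <- block_design(7, 15, 2, 2.5, 100)
  expect_error(block_regressor(d, ratio = "strict"), "integer multiples")
  expect_silent(block_regressor(d, ratio = "round"))
})

test_that("hybrid slice has the published geometry and is reproducible", {
  h <- generate_hybrid_slice(cnr = 2, seed = 4)
  expect_equal(sum(h$vs$mask), 1212)
  expect_equal(sum(h$truth), 25)
  expect_equal(dim(h$vs$data), c(64L, 64L, 1L, 140L))
  # activation voxels are inside the mask
  expect_true(all(h$vs$mask[h$truth == 1L]))

  h2 <- generate_hybrid_slice(cnr = 2, seed = 4)
  expect_identical(h$vs$data, h2$vs$data)
  h3 <- generate_hybrid_slice(cnr = 2, seed = 5)
  expect_false(identical(h$vs$data, h3$vs$data))
})

test_that("zero contrast leaves active and background voxels exchangeable", {
  h <- generate_hybrid_slice(cnr = 0, seed = 2)
  act <- which(h$truth == 1L)
  bg <- setdiff(which(h$vs$mask), act)
  flat <- matrix(h$vs$data, 64 * 64, 140)
  # per-voxel temporal sd should have the same distribution
  sd_act <- apply(flat[act, ], 1, sd)
  sd_bg <- apply(flat[bg, ], 1, sd)
  expect_lt(abs(mean(sd_act) - mean(sd_bg)), 3 * sd(sd_bg) / sqrt(25))
})

test_that("empirical CNR matches the requested CNR within sampling error", {
  # boxcar waveform so (mean ON - mean OFF) estimates the contrast directly
  ests <- vapply(1:4, function(s) {
    h <- generate_hybrid_slice(cnr = 1.66, seed = 100 + s,
                               waveform = "boxcar", noise_sd = 2)
    flat <- matrix(h$vs$data, 64 * 64, 140)
    act <- flat[h$truth == 1L, , drop = FALSE]
    on <- h$regressor == 1
    mean(rowMeans(act[, on]) - rowMeans(act[, !on])) / 2
  }, numeric(1))
  # se of the contrast estimate: noise sd 1 (normalised), 25 voxels (but
  # spatially correlated, so budget ~6 effective), 140 frames
  se <- 1 / sqrt(6 * 70) / sqrt(4)
  expect_lt(abs(mean(ests) - 1.66), 3 * se + 0.02)
})

test_that("network phantom enforces its preconditions and truth structure", {
  sources <- matrix(rnorm(40), 20)
  roi <- function(x0) list(voxels = as.matrix(expand.grid(x0:(x0 + 1), 1:2, 1:2)),
                           mixing = c(1, 0), cnr = 1)
  expect_error(generate_network_phantom(c(6, 6, 3), 20,
                                        list(roi(1), roi(2)), sources),
               "overlapping")
  bad <- list(list(voxels = cbind(9L, 1L, 1L), mixing = c(1, 0), cnr = 1))
  expect_error(generate_network_phantom(c(6, 6, 3), 20, bad, sources),
               "outside")

  ph <- default_network_phantom(seed = 3)
  # truth labels partition exactly the declared ROI voxels
  expect_equal(sum(ph$truth > 0), 5 * 18)
  expect_equal(sort(unique(as.integer(ph$truth))), 0:5)
  # source sharing: 3-clique (ROIs 1-3) and 2-clique (ROIs 4-5)
  expect_equal(ph$truth_adjacency[1:3, 1:3] - (1 - diag(3)) * 0,
               matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3))
  expect_equal(ph$truth_adjacency[4, 5], 1L)
  expect_true(all(ph$truth_adjacency[1:3, 4:5] == 0L))
})

test_that("noiseless phantom has within-ROI correlation 1", {
  sources <- matrix(rnorm(60), 30)
  # CNR -> infinity is the noiseless limit (the contrast amplitude is
  # cnr * noise_sd, so shrinking noise_sd alone keeps r fixed at
  # cnr^2 v / (cnr^2 v + 1))
  rois <- list(list(voxels = as.matrix(expand.grid(2:3, 2:3, 1:2)),
                    mixing = c(1, 0), cnr = 1e5))
  ph <- generate_network_phantom(c(6, 6, 3), 30, rois, sources,
                                 noise_sd = 1, fwhm_mm = c(0, 0, 0),
                                 seed = 2)
  flat <- matrix(ph$vs$data, prod(dim(ph$truth)), 30)
  cc <- cor(t(flat[ph$truth == 1L, ]))
  expect_true(all(cc > 1 - 1e-6))
})

test_that("generator/estimator FWHM round trip recovers applied smoothing", {
  # pure-noise phantom smoothed at 8 mm (about 2.7 voxels at 3 mm)
  ph <- generate_network_phantom(c(24L, 24L, 12L), 40, list(),
                                 matrix(0, 40, 1), noise_sd = 1,
                                 fwhm_mm = c(8, 8, 8), seed = 9)
  fw <- estimate_fwhm(ph$vs)
  expect_true(all(abs(fw - 8) / 8 < 0.15))
})
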
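test_that("sphere offsets enumerate the lattice ball exactly", {
  o1 <- sphere_offsets(2, c(2, 2, 2))
  expect_equal(nrow(o1), 7L)
  o2 <- sphere_offsets(0, c(1, 1, 1))
  expect_equal(nrow(o2), 1L)
  expect_equal(as.numeric(o2), c(0, 0, 0))
  o3 <- sphere_offsets(2, c(1, 1, 1))
  expect_equal(nrow(o3), 33L)

  # brute-force lattice enumeration oracle over a generous bounding box
  for (case in list(list(r = 2, vs = c(2, 2, 2)),
                    list(r = 2, vs = c(1, 1, 1)),
                    list(r = 3.5, vs = c(1.5, 2, 1)))) {
    g <- as.matrix(expand.grid(dx = -6:6, dy = -6:6, dz = -6:6))
    keep <- sqrt((g[, 1] * case$vs[1])^2 + (g[, 2] * case$vs[2])^2 +
                   (g[, 3] * case$vs[3])^2) <= case$r + 1e-9
    got <- sphere_offsets(case$r, case$vs)
    expect_equal(nrow(got), sum(keep))
    expect_setequal(paste(got[, 1], got[, 2], got[, 3]),
                    paste(g[keep, 1], g[keep, 2], g[keep, 3]))
  }
  expect_error(sphere_offsets(-1, 1), "non-negative")
})

test_that("null data decodes at chance and rarely crosses the 70% cut", {
  nl <- null_two_group(n = 16, grid = c(14L, 14L, 14L), seed = 41)
  fm <- build_feature_matrix(nl$cohort)
  set.seed(1)
  centers <- fm$voxels[sample(nrow(fm$voxels), 60), ]
  amap <- searchlight_accuracy_map(nl$cohort, searchlight_config(seed = 41),
                                   centers = centers)
  vals <- amap$accuracy$data[centers]
  expect_true(all(vals >= 0 & vals <= 1))
  expect_lt(abs(mean(vals) - 0.5), 0.1)
  expect_lte(mean(vals > 0.7), 0.1)
})

test_that("strongly affected voxels decode nearly perfectly", {
  sim <- simulate_cohort(default_scenario(seed = 42))
  coh <- subset_cohort(sim$cohort, c("ET", "NC"))
  support <- which(sim$truth$ET_vs_NC$effect_map$data != 0, arr.ind = TRUE)
  set.seed(2)
  centers <- support[sample(nrow(support), 20), ]
  amap <- searchlight_accuracy_map(coh, searchlight_config(seed = 42),
                                   centers = centers)
  expect_true(all(amap$accuracy$data[centers] >= 0.9))
})

test_that("the accuracy map is deterministic and intensity-scale invariant", {
  nl <- null_two_group(n = 8, grid = c(12L, 12L, 12L), seed = 7)
  fm <- build_feature_matrix(nl$cohort)
  centers <- fm$voxels[seq(1, nrow(fm$voxels), length.out = 10), , drop = FALSE]
  cfg <- searchlight_config(n_folds = 4, seed = 7)
  a1 <- searchlight_accuracy_map(nl$cohort, cfg, centers)
  a2 <- searchlight_accuracy_map(nl$cohort, cfg, centers)
  expect_identical(a1$accuracy$data, a2$accuracy$data)

  scaled <- nl$cohort
  scaled$data <- 3 * scaled$data + 5
  a3 <- searchlight_accuracy_map(scaled, cfg, centers)
  expect_equal(a3$accuracy$data, a1$accuracy$data, tolerance = 1e-12)
})

test_that("spheres truncate at the mask boundary instead of skipping", {
  nl <- null_two_group(n = 8, grid = c(12L, 12L, 12L), seed = 8)
  mask <- nl$cohort$mask
  # an extreme mask voxel is on the boundary: its ball is truncated
  vox <- which(mask, arr.ind = TRUE)
  edge <- vox[which.min(vox[, 1]), , drop = FALSE]
  amap <- searchlight_accuracy_map(nl$cohort, searchlight_config(seed = 8),
                                   centers = edge)
  expect_lt(amap$n_features[edge], 7)
  expect_gt(amap$n_features[edge], 0)
})

test_that("accuracy thresholding is strict and extent-filtered", {
  d <- c(12, 12, 12)
  acc <- array(0, d)
  centers <- which(array(TRUE, d), arr.ind = TRUE)
  acc[2:6, 2:5, 2:4] <- 0.95            # 60 voxels
  acc[9:10, 9, 8:12] <- 0.95            # 10 voxels
  amap <- structure(list(accuracy = volume(acc, diag(4)),
                         n_features = array(7L, d), centers = centers),
                    class = "accuracy_map")
  cs <- threshold_accuracy_map(amap, searchlight_config(min_cluster = 50))
  expect_length(cs$clusters, 1L)
  expect_equal(cs$clusters[[1]]$size, 60L)

  acc2 <- array(0.5, d)
  amap$accuracy <- volume(acc2, diag(4))
  expect_length(threshold_accuracy_map(amap)$clusters, 0L)

  acc3 <- array(0, d)
  acc3[2:6, 2:5, 2:4] <- 0.7            # exactly at the threshold
  amap$accuracy <- volume(acc3, diag(4))
  expect_length(threshold_accuracy_map(
    amap, searchlight_config(min_cluster = 10))$clusters, 0L)
})
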
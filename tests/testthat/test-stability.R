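test_that("atlas splitting partitions clusters exactly", {
  atl <- make_atlas(c(14, 14, 14), 1.5, 4, seed = 13)
  vox1 <- which(atl$labels == 1)
  vox2 <- which(atl$labels == 2)
  mask <- array(FALSE, c(14, 14, 14))
  mask[vox1[1:30]] <- TRUE
  mask[vox2[1:70]] <- TRUE
  sv <- volume(array(1, dim(mask)), atl$affine)
  cs <- extract_clusters(sv, mask, min_size = 1, connectivity = 26)
  subs <- split_clusters_by_atlas(cs, atl)
  # conservation: sub-cluster sizes sum to parent sizes
  parent_sizes <- vapply(cs$clusters, `[[`, 0L, "size")
  for (i in seq_along(cs$clusters)) {
    expect_equal(sum(vapply(subs[vapply(subs, `[[`, 0L, "parent") == i],
                            `[[`, 0L, "size")), parent_sizes[i])
  }
  # a cluster fully inside one parcel maps to a single identical sub-cluster
  mask2 <- array(FALSE, c(14, 14, 14))
  mask2[vox1[1:25]] <- TRUE
  cs2 <- extract_clusters(sv, mask2, min_size = 1)
  subs2 <- split_clusters_by_atlas(cs2, atl)
  one <- subs2[vapply(subs2, `[[`, 0L, "parent") == 1L]
  expect_length(one, 1L)
  expect_equal(one[[1]]$size, cs2$clusters[[1]]$size)
  expect_false(one[[1]]$unlabeled)
})

test_that("the empirical p-value follows the add-one permutation formula", {
  expect_equal(permutation_pvalue(0.9, rep(0.5, 99)), 0.01)
  expect_equal(permutation_pvalue(0.9, c(rep(0.95, 9), rep(0.5, 90))), 0.10)
  expect_equal(permutation_pvalue(0.5, rep(0.9, 9)), 1)
  expect_error(permutation_pvalue(0.5, numeric(0)), "at least one")

  # brute-force recount oracle over random permutation records
  set.seed(99)
  for (i in 1:50) {
    k <- sample(20:200, 1)
    obs <- sample(seq(0, 1, by = 0.05), 1)
    perms <- sample(seq(0, 1, by = 0.05), k, replace = TRUE)
    count <- 0L
    for (p in perms) if (p >= obs) count <- count + 1L
    expect_identical(permutation_pvalue(obs, perms), (count + 1) / (k + 1))
  }
})

test_that("the p-value is monotone in the observed accuracy", {
  set.seed(3)
  perms <- sample(seq(0, 1, 0.1), 199, replace = TRUE)
  grid <- seq(0, 1, 0.05)
  ps <- vapply(grid, permutation_pvalue, 0, permuted = perms)
  expect_true(all(diff(ps) <= 0))
  expect_true(all(ps >= 1 / 200 & ps <= 1))
})

test_that("permutation config enforces attainability of the threshold", {
  expect_error(permutation_config(k = 50, p_threshold = 0.01), "attain")
  expect_silent(permutation_config(k = 99, p_threshold = 0.01))
  expect_error(permutation_config(k = 0), "at least 1")
})

test_that("sub-cluster scoring separates signal from chance", {
  sim <- simulate_cohort(default_scenario(seed = 17))
  coh <- subset_cohort(sim$cohort, c("ET", "NC"))
  support <- which(sim$truth$ET_vs_NC$effect_map$data > 0, arr.ind = TRUE)
  vox <- support[1:min(40, nrow(support)), , drop = FALSE]
  acc <- subcluster_accuracy(coh, vox, seed = 17)
  expect_gte(acc, 0.9)

  pcfg <- permutation_config(k = 19, p_threshold = 0.05, seed = 17)
  pt <- permutation_test(coh, vox, pcfg, fold_seed = 17)
  expect_equal(pt$observed, acc)
  expect_equal(pt$p, permutation_pvalue(pt$observed, pt$permuted))
  expect_equal(pt$p, 1 / 20)
  # permuted accuracies sit near chance
  expect_lt(abs(mean(pt$permuted) - 0.5), 0.15)

  pt2 <- permutation_test(coh, vox, pcfg, fold_seed = 17)
  expect_identical(pt2$permuted, pt$permuted)
})

test_that("biomarker selection applies both the p and the size rule", {
  scored <- data.frame(
    subcluster_id = 1:4, cluster_id = c(1, 1, 2, 2),
    label = 1:4, region = paste0("P0", 1:4),
    unlabeled = c(FALSE, FALSE, FALSE, TRUE),
    x = 0, y = 0, z = 0,
    size = c(49L, 400L, 120L, 200L),
    accuracy = c(0.95, 0.9, 0.92, 0.99),
    perm_p = c(0.009, 0.02, 0.01, 0.005))
  subclusters <- lapply(1:4, function(i) {
    list(voxels = matrix(c(i, i, i), 1), size = scored$size[i])
  })
  sel <- select_biomarkers(scored, subclusters, c(6, 6, 6))
  # p ok but too small; size ok but p too large; both ok; unlabeled dropped
  expect_equal(sel$report$subcluster_id, 3L)
  expect_equal(sum(sel$mask), 1L)
  sel2 <- select_biomarkers(scored, subclusters, c(6, 6, 6),
                            include_unlabeled = TRUE)
  expect_setequal(sel2$report$subcluster_id, c(3L, 4L))
})

test_that("the biomarker mask stays inside the model-level clusters", {
  sim <- simulate_cohort(default_scenario(seed = 19))
  res <- find_biomarkers(sim$cohort, sim$atlas, "ET", "NC",
                         sl_config = searchlight_config(seed = 19),
                         perm_config = permutation_config(k = 99, seed = 19))
  cm <- cluster_mask(res$clusters)
  expect_true(all(cm[res$mask]))
  # scored accuracies are reproduced by the standalone scorer
  coh <- subset_cohort(sim$cohort, c("ET", "NC"))
  for (i in res$report$subcluster_id[seq_len(min(2, nrow(res$report)))]) {
    sc <- res$subclusters[[i]]
    expect_equal(subcluster_accuracy(coh, sc$voxels, seed = 19),
                 res$scored$accuracy[res$scored$subcluster_id == i])
  }
})
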
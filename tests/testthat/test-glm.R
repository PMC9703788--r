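random_two_group_cohort <- function(n_per = 6L, d = c(3, 3, 3), seed = 1) {
  set.seed(seed)
  n <- 2L * n_per
  cohort(array(rnorm(prod(d) * n), c(d, n)),
         rep(c("ET", "NC"), each = n_per),
         data.frame(age = rnorm(n, 60, 8), sex = rep_len(0:1, n),
                    tiv = rnorm(n, 1400, 120)),
         array(TRUE, d))
}

test_that("covariate-free GLM t equals the pooled two-sample t everywhere", {
  coh <- random_two_group_cohort(seed = 4)
  res <- fit_glm_tmap(coh, "ET", "NC", covariates = character(0))
  y <- coh$groups
  for (lin in seq_len(27)) {
    v <- arrayInd(lin, c(3, 3, 3))
    vals <- coh$data[v[1], v[2], v[3], ]
    tt <- stats::t.test(vals[y == "ET"], vals[y == "NC"], var.equal = TRUE)
    expect_equal(res$tmap$data[v], unname(tt$statistic), tolerance = 1e-10)
  }
  expect_equal(res$dof, 10L)
})

test_that("toy contrast {1,2,3} vs {4,5,6} reproduces the closed-form t", {
  d <- c(2, 2, 2)
  dat <- array(0, c(d, 6))
  for (i in 1:6) dat[, , , i] <- i
  coh <- cohort(dat, rep(c("ET", "NC"), each = 3),
                data.frame(age = rnorm(6, 60), sex = rep_len(0:1, 6),
                           tiv = rep(1400, 6)),
                array(TRUE, d))
  res <- fit_glm_tmap(coh, "ET", "NC", covariates = character(0))
  # normal-equations oracle: mean diff -3, pooled sd 1, se = sqrt(2/3)
  expect_equal(res$tmap$data[1, 1, 1], -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(round(res$tmap$data[1, 1, 1], 3), -3.674)
})

test_that("GLM matches a brute-force lm oracle with covariates", {
  coh <- random_two_group_cohort(n_per = 8, seed = 9)
  res <- fit_glm_tmap(coh, "ET", "NC")
  g <- as.numeric(coh$groups == "ET")
  set.seed(2)
  for (lin in sample(27, 5)) {
    v <- arrayInd(lin, c(3, 3, 3))
    df <- data.frame(y = coh$data[v[1], v[2], v[3], ], g = g,
                     coh$covariates)
    fit <- stats::lm(y ~ g + age + sex + tiv, df)
    expect_equal(res$tmap$data[v],
                 unname(summary(fit)$coefficients["g", "t value"]),
                 tolerance = 1e-10)
  }
  expect_equal(res$dof, 16L - 5L)
})

test_that("a covariate orthogonal to group and response rescales t by dof", {
  d <- c(1, 1, 1)
  n <- 12L
  set.seed(5)
  yv <- rnorm(n)
  g <- rep(c(1, 0), each = n / 2)
  # age orthogonalised against intercept, group and the response
  raw <- rnorm(n)
  ortho <- stats::resid(stats::lm(raw ~ g + yv))
  coh <- cohort(array(yv, c(d, n)), rep(c("ET", "NC"), each = n / 2),
                data.frame(age = ortho, sex = rep_len(0:1, n),
                           tiv = rep(1400, n)),
                array(TRUE, d))
  t0 <- fit_glm_tmap(coh, "ET", "NC", covariates = character(0))
  t1 <- fit_glm_tmap(coh, "ET", "NC", covariates = "age")
  # beta and RSS are untouched, so only the dof in sigma^2 moves the t
  expect_equal(t1$tmap$data[1, 1, 1],
               t0$tmap$data[1, 1, 1] * sqrt((n - 3) / (n - 2)),
               tolerance = 1e-10)
  expect_equal(t1$dof, t0$dof - 1L)
})

test_that("swapping the groups negates the t-map exactly", {
  coh <- random_two_group_cohort(seed = 12)
  a <- fit_glm_tmap(coh, "ET", "NC")
  b <- fit_glm_tmap(coh, "NC", "ET")
  expect_equal(a$tmap$data, -b$tmap$data)
})

test_that("zero-variance voxels get t = 0 and rank deficiency is named", {
  coh <- random_two_group_cohort(seed = 3)
  coh$data[1, 1, 1, ] <- 5
  res <- fit_glm_tmap(coh, "ET", "NC", covariates = character(0))
  expect_equal(res$tmap$data[1, 1, 1], 0)
  cs <- threshold_tmap(res, "greater", 0.5, min_cluster = 1)
  expect_false(any(vapply(cs$clusters, function(cl) {
    any(cl$voxels[, 1] == 1 & cl$voxels[, 2] == 1 & cl$voxels[, 3] == 1)
  }, TRUE)))

  coh$covariates$sex <- 1
  expect_error(fit_glm_tmap(coh, "ET", "NC"), "sex")
})

test_that("thresholding an all-zero map finds nothing", {
  coh <- random_two_group_cohort(seed = 6)
  res <- fit_glm_tmap(coh, "ET", "NC")
  res$tmap$data[] <- 0
  expect_length(threshold_tmap(res, "greater")$clusters, 0L)
})

test_that("strong parcel effects are recovered by the t-map branch", {
  sim <- simulate_cohort(default_scenario(seed = 31))
  res <- fit_glm_tmap(sim$cohort, "ET", "NC")
  truth <- sim$truth$ET_vs_NC
  up <- threshold_tmap(res, "greater", min_cluster = 20)
  dn <- threshold_tmap(res, "less", min_cluster = 20)
  covered <- cluster_mask(up) | cluster_mask(dn)
  for (p in truth$parcels) {
    expect_gt(sum(covered & sim$atlas$labels == p), 0)
  }
})

test_that("cluster reports name regions by descending overlap", {
  atl <- make_atlas(c(14, 14, 14), 1.5, 4, seed = 2)
  # build one cluster spanning two parcels with 70/30 voxels
  vox1 <- which(atl$labels == 1)
  vox2 <- which(atl$labels == 2)
  mask <- array(FALSE, c(14, 14, 14))
  mask[vox1[1:30]] <- TRUE
  mask[vox2[1:70]] <- TRUE
  sv <- volume(array(as.numeric(mask), dim(mask)), atl$affine)
  cs <- extract_clusters(sv, mask, min_size = 1, connectivity = 26)
  rep <- cluster_report(cs, atl)
  expect_equal(nrow(rep), length(cs$clusters))
  row_both <- rep[grepl(",", rep$regions), ]
  if (nrow(row_both) == 1L) {
    expect_equal(row_both$regions, "P02,P01")
  }
  # single-parcel cluster reports exactly that parcel
  mask2 <- array(FALSE, c(14, 14, 14))
  mask2[vox1[1:25]] <- TRUE
  cs2 <- extract_clusters(sv, mask2, min_size = 1)
  rep2 <- cluster_report(cs2, atl)
  expect_true(all(rep2$regions == "P01"))
})
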
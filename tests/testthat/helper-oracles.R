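# Independent oracles and fixture builders used across the suite.

# Connected components via pairwise adjacency + igraph, independent of the
# package's flood fill.
oracle_components <- function(mask, connectivity) {
  lin <- which(mask)
  m <- length(lin)
  if (m == 0L) return(list())
  co <- arrayInd(lin, dim(mask))
  cheb <- as.matrix(stats::dist(co, method = "maximum"))
  manh <- as.matrix(stats::dist(co, method = "manhattan"))
  adj <- switch(as.character(connectivity),
                "6"  = manh == 1,
                "18" = cheb == 1 & manh <= 2,
                "26" = cheb == 1)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  memb <- igraph::components(g)$membership
  # canonical form: sorted list of sorted member linear-index vectors
  comps <- split(lin, memb)
  comps <- lapply(comps, sort)
  comps[order(vapply(comps, min, 0))]
}

# Canonical form of a package cluster_set (no min-size filter applied).
canonical_clusters <- function(cs) {
  comps <- lapply(cs$clusters, function(cl) {
    sort((cl$voxels[, 3] - 1L) * cs$dim[1] * cs$dim[2] +
           (cl$voxels[, 2] - 1L) * cs$dim[1] + cl$voxels[, 1])
  })
  comps[order(vapply(comps, min, 0))]
}

# Pairwise-comparison AUC oracle, O(P*Q), exact tie handling.
oracle_auc <- function(scores, labels, positive) {
  s1 <- scores[labels == positive]
  s0 <- scores[labels != positive]
  (sum(outer(s1, s0, ">")) + 0.5 * sum(outer(s1, s0, "=="))) /
    (length(s1) * length(s0))
}

# Direct truncated-kernel convolution at one interior voxel.
oracle_smooth_at <- function(data, voxel, sigma_vox) {
  r <- ceiling(4 * sigma_vox)
  k1 <- function(s) {
    x <- seq(-ceiling(4 * s), ceiling(4 * s))
    k <- exp(-x^2 / (2 * s^2))
    k / sum(k)
  }
  kx <- k1(sigma_vox[1]); ky <- k1(sigma_vox[2]); kz <- k1(sigma_vox[3])
  acc <- 0
  for (ix in seq_along(kx)) for (iy in seq_along(ky)) for (iz in seq_along(kz)) {
    p <- voxel + c(ix - ceiling(4 * sigma_vox[1]) - 1,
                   iy - ceiling(4 * sigma_vox[2]) - 1,
                   iz - ceiling(4 * sigma_vox[3]) - 1)
    acc <- acc + kx[ix] * ky[iy] * kz[iz] * data[p[1], p[2], p[3]]
  }
  acc
}

# Small null (no group effect) simulated study, ET/NC subset.
null_two_group <- function(n = 16L, grid = c(14L, 14L, 14L),
                           n_parcels = 8L, seed = 1L, smooth_fwhm = 2) {
  cfg <- sim_config(grid_shape = grid,
                    n_per_group = c(NC = n, ET = n, PD = 2L),
                    n_parcels = n_parcels, smooth_fwhm = smooth_fwhm,
                    seed = seed)
  sim <- simulate_cohort(cfg)
  list(cohort = subset_cohort(sim$cohort, c("ET", "NC")),
       atlas = sim$atlas, sim = sim)
}

# Well-separated two-class gaussian feature matrix.
separable_features <- function(n_per = 16L, p = 30L, delta = 4, seed = 1L) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * p), n_per, p),
             matrix(rnorm(n_per * p, mean = delta), n_per, p))
  list(X = X, y = factor(rep(c("ET", "PD"), each = n_per)))
}
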
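#' Searchlight sphere offsets
#'
#' Enumerates every integer voxel offset whose centre-to-centre world
#' distance is within `radius` mm, including the centre itself, in
#' deterministic lexicographic (x, y, z) order.  With 2 mm isotropic voxels
#' a 2 mm radius yields the centre plus its 6 face neighbours.
#'
#' @param radius sphere radius in mm (>= 0).
#' @param voxel_size voxel edge length(s) in mm (scalar or length 3).
#' @return integer `n_offsets x 3` matrix.
#' @export
sphere_offsets <- function(radius, voxel_size) {
  if (radius < 0) stop("radius must be non-negative")
  voxel_size <- rep_len(voxel_size, 3L)
  rmax <- floor(radius / voxel_size)
  g <- as.matrix(expand.grid(dz = -rmax[3]:rmax[3],
                             dy = -rmax[2]:rmax[2],
                             dx = -rmax[1]:rmax[1]))[, 3:1, drop = FALSE]
  d2 <- (g[, 1] * voxel_size[1])^2 + (g[, 2] * voxel_size[2])^2 +
    (g[, 3] * voxel_size[3])^2
  g <- g[d2 <= radius^2 + 1e-9, , drop = FALSE]
  g <- g[order(g[, 1], g[, 2], g[, 3]), , drop = FALSE]
  colnames(g) <- c("dx", "dy", "dz")
  g
}

#' Searchlight configuration
#'
#' @param radius searchlight sphere radius in mm (default 2).
#' @param variance_retained PCA explained-variance fraction (default 0.8).
#' @param n_folds cross-validation folds (default 5).
#' @param cost linear-SVM regularisation C (default 1).
#' @param accuracy_threshold accuracy cut for cluster formation, strict
#'   (default 0.7).
#' @param min_cluster minimum cluster extent (default 50).
#' @param connectivity cluster connectivity (default 26).
#' @param pca_leaky fit PCA on all rows instead of training folds only
#'   (default `FALSE`; see [cv_pca_svm()]).
#' @param seed seed for the fold assignment.
#' @return list of class `searchlight_config`.
#' @export
searchlight_config <- function(radius = 2, variance_retained = 0.8,
                               n_folds = 5L, cost = 1,
                               accuracy_threshold = 0.7, min_cluster = 50L,
                               connectivity = 26L, pca_leaky = FALSE,
                               seed = 1L) {
  stopifnot(radius >= 0, variance_retained > 0, variance_retained <= 1,
            n_folds >= 2L, accuracy_threshold > 0, accuracy_threshold < 1)
  structure(list(radius = radius, variance_retained = variance_retained,
                 n_folds = as.integer(n_folds), cost = cost,
                 accuracy_threshold = accuracy_threshold,
                 min_cluster = as.integer(min_cluster),
                 connectivity = as.integer(connectivity),
                 pca_leaky = pca_leaky, seed = as.integer(seed)),
            class = "searchlight_config")
}

#' Searchlight cross-validated accuracy map
#'
#' The model-level assessment: a sphere of the configured radius slides over
#' every in-mask voxel; the sphere's in-mask voxels form the feature set of
#' a PCA+SVM classifier (PCA retaining the configured variance fraction,
#' fitted within training folds), and the voxel is scored by mean stratified
#' k-fold cross-validated accuracy of patient-versus-control decoding.
#' Spheres are truncated at the mask boundary rather than skipped.  One
#' stratified fold assignment, drawn from `config$seed`, is reused for every
#' centre, so the map is reproducible and fold noise is shared across
#' centres.
#'
#' @param coh a [cohort()] restricted to exactly two groups (see
#'   [subset_cohort()]); each class must have at least `n_folds` subjects.
#' @param config a [searchlight_config()].
#' @param centers optional integer `m x 3` matrix of centre voxels to score
#'   (defaults to every in-mask voxel); centres outside the mask are
#'   rejected.
#' @return an `accuracy_map`: list with `accuracy` (a [volume()] of mean CV
#'   accuracy, 0 outside the scored centres), `n_features` (voxels per
#'   sphere, same layout), `centers`, and the `fold_id` used.
#' @export
searchlight_accuracy_map <- function(coh, config = searchlight_config(),
                                     centers = NULL) {
  y <- droplevels(coh$groups)
  if (nlevels(y) != 2L) stop("searchlight needs a two-group cohort")
  if (min(table(y)) < config$n_folds) {
    stop("smallest class is below n_folds = ", config$n_folds)
  }
  d <- dim(coh$mask)
  fm <- build_feature_matrix(coh)
  col_of <- integer(prod(d))
  lin_mask <- which(coh$mask)
  col_of[lin_mask] <- seq_along(lin_mask)
  if (is.null(centers)) {
    centers <- fm$voxels
  } else {
    centers <- matrix(as.integer(centers), ncol = 3L)
    if (any(!coh$mask[centers])) stop("all centers must lie inside the mask")
  }
  offs <- sphere_offsets(config$radius, voxel_size(subject_volume(coh, 1L)))
  fold_id <- make_folds(y, config$n_folds, config$seed)

  acc <- array(0, d)
  nfeat <- array(0L, d)
  s2 <- d[1]
  s3 <- d[1] * d[2]
  for (i in seq_len(nrow(centers))) {
    cx <- centers[i, 1] + offs[, 1]
    cy <- centers[i, 2] + offs[, 2]
    cz <- centers[i, 3] + offs[, 3]
    ok <- cx >= 1L & cx <= d[1] & cy >= 1L & cy <= d[2] & cz >= 1L & cz <= d[3]
    cols <- col_of[(cx[ok] - 1L) + (cy[ok] - 1L) * s2 + (cz[ok] - 1L) * s3 + 1L]
    cols <- cols[cols > 0L]
    ci <- centers[i, , drop = FALSE]
    nfeat[ci] <- length(cols)
    acc[ci] <- cv_pca_svm(fm$X[, cols, drop = FALSE], y, fold_id,
                          config$variance_retained, config$cost,
                          config$pca_leaky)
  }
  structure(list(accuracy = volume(acc, coh$affine),
                 n_features = nfeat, centers = centers, fold_id = fold_id),
            class = "accuracy_map")
}

#' @export
print.accuracy_map <- function(x, ...) {
  v <- x$accuracy$data[x$centers]
  cat(sprintf("<accuracy_map> %d centers, accuracy %.2f-%.2f (mean %.3f)\n",
              nrow(x$centers), min(v), max(v), mean(v)))
  invisible(x)
}

#' Threshold an accuracy map into candidate clusters
#'
#' Keeps centres whose decoding accuracy strictly exceeds the threshold
#' (accuracy > 70% by default) and applies cluster-extent filtering,
#' yielding the model-level candidate regions.
#'
#' @param amap an `accuracy_map` from [searchlight_accuracy_map()].
#' @param config a [searchlight_config()] supplying
#'   `accuracy_threshold`, `min_cluster` and `connectivity`.
#' @return a `cluster_set`.
#' @export
threshold_accuracy_map <- function(amap, config = searchlight_config()) {
  supra <- array(FALSE, dim(amap$accuracy$data))
  supra[amap$centers] <- amap$accuracy$data[amap$centers] >
    config$accuracy_threshold
  extract_clusters(amap$accuracy, supra, min_size = config$min_cluster,
                   connectivity = config$connectivity)
}
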
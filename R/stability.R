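#' Split searchlight clusters along atlas boundaries
#'
#' The feature-level assessment starts by partitioning every model-level
#' cluster by parcellation label, so that a cluster straddling an anatomical
#' boundary is decomposed into per-region sub-clusters (voxels on the atlas
#' background form their own sub-cluster flagged `unlabeled`).  The union of
#' a cluster's sub-clusters is exactly the cluster.
#'
#' @param clusters a `cluster_set` from [threshold_accuracy_map()] (or any
#'   [extract_clusters()] result).
#' @param atl an [atlas()] on the same grid.
#' @return list of sub-clusters, each a list with `voxels`, `size`,
#'   `parent`, `label`, `region`, `unlabeled`.
#' @export
split_clusters_by_atlas <- function(clusters, atl) {
  if (!identical(dim(atl$labels), clusters$dim)) {
    stop("atlas grid does not match cluster grid")
  }
  out <- list()
  for (i in seq_along(clusters$clusters)) {
    cl <- clusters$clusters[[i]]
    labs <- atl$labels[cl$voxels]
    for (lab in sort(unique(labs))) {
      vox <- cl$voxels[labs == lab, , drop = FALSE]
      out[[length(out) + 1L]] <- list(
        voxels = vox, size = nrow(vox), parent = i, label = lab,
        region = region_name(atl, lab), unlabeled = lab == 0L)
    }
  }
  out
}

#' Cross-validated accuracy of one sub-cluster
#'
#' Scores a sub-cluster's voxels as a feature set with the same stratified
#' PCA+SVM cross-validation protocol as the searchlight.
#'
#' @param coh two-group [cohort()].
#' @param voxels integer `n x 3` voxel index matrix.
#' @param n_folds,variance_retained,cost,seed protocol parameters (defaults
#'   5 folds, 80% variance, C = 1).
#' @return mean CV accuracy in `[0, 1]`.
#' @export
subcluster_accuracy <- function(coh, voxels, n_folds = 5L,
                                variance_retained = 0.8, cost = 1,
                                seed = 1L) {
  if (!nrow(voxels)) stop("sub-cluster is empty")
  y <- droplevels(coh$groups)
  fold_id <- make_folds(y, n_folds, seed)
  X <- voxel_features(coh, voxels)
  cv_pca_svm(X, y, fold_id, variance_retained, cost)
}

voxel_features <- function(coh, voxels) {
  n <- n_subjects(coh)
  X <- matrix(0, n, nrow(voxels))
  for (s in seq_len(n)) X[s, ] <- coh$data[, , , s][voxels]
  X
}

#' Permutation-test configuration
#'
#' @param k number of label randomisations (default 999; the smallest
#'   attainable p is `1/(k+1)`, so `k` must be at least
#'   `ceiling(1/p_threshold) - 1` for `p_threshold` to be reachable).
#' @param p_threshold selection threshold on the empirical p (default 0.01).
#' @param min_size minimum sub-cluster extent in voxels (default 50).
#' @param seed seed for the randomisations.
#' @return list of class `permutation_config`.
#' @export
permutation_config <- function(k = 999L, p_threshold = 0.01, min_size = 50L,
                               seed = 1L) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be at least 1")
  if (k < ceiling(1 / p_threshold) - 1) {
    stop("k = ", k, " cannot attain p_threshold = ", p_threshold,
         "; need k >= ", ceiling(1 / p_threshold) - 1)
  }
  structure(list(k = k, p_threshold = p_threshold,
                 min_size = as.integer(min_size), seed = as.integer(seed)),
            class = "permutation_config")
}

#' Empirical permutation p-value of a classifier accuracy
#'
#' The add-one empirical p-value: with `k` accuracies obtained on
#' label-randomised data, `p = (#\{permuted >= observed\} + 1) / (k + 1)`.
#' The comparison is `>=` and exact (CV accuracies are small-denominator
#' rationals), and the smallest attainable value is `1/(k+1)`.
#'
#' @param observed accuracy on the original labels.
#' @param permuted numeric vector of `k` accuracies on permuted labels.
#' @return empirical p-value in `[1/(k+1), 1]`.
#' @export
permutation_pvalue <- function(observed, permuted) {
  k <- length(permuted)
  if (k < 1L) stop("need at least one permutation accuracy")
  (sum(permuted >= observed) + 1) / (k + 1)
}

#' Label-permutation test for a sub-cluster
#'
#' Recomputes the full stratified CV accuracy under `k` random relabelings
#' of the subjects — each permutation shuffles the labels once and
#' re-stratifies the fold assignment on the permuted labels — and returns
#' the empirical p of the observed accuracy.
#'
#' @param coh two-group [cohort()].
#' @param voxels integer `n x 3` voxel index matrix of the sub-cluster.
#' @param config a [permutation_config()].
#' @param n_folds,variance_retained,cost CV protocol parameters.
#' @param fold_seed seed of the observed-accuracy fold assignment.
#' @return list with `observed`, `permuted` (length `k`), and `p`.
#' @export
permutation_test <- function(coh, voxels, config = permutation_config(),
                             n_folds = 5L, variance_retained = 0.8,
                             cost = 1, fold_seed = 1L) {
  y <- droplevels(coh$groups)
  X <- voxel_features(coh, voxels)
  observed <- cv_pca_svm(X, y, make_folds(y, n_folds, fold_seed),
                         variance_retained, cost)
  permuted <- numeric(config$k)
  perm_seeds <- derive_seeds(config$seed, config$k + 1L)
  with_seed(perm_seeds[config$k + 1L], {
    for (j in seq_len(config$k)) {
      yp <- y[sample.int(length(y))]
      permuted[j] <- cv_pca_svm(X, yp, make_folds(yp, n_folds, perm_seeds[j]),
                                variance_retained, cost)
    }
  })
  list(observed = observed, permuted = permuted,
       p = permutation_pvalue(observed, permuted))
}

#' Score sub-clusters with CV accuracy and permutation p
#'
#' Runs [subcluster_accuracy()] and [permutation_test()] on every
#' sub-cluster and assembles the feature-level record: region, size, peak
#' (maximal accuracy-map value within the sub-cluster, lexicographic
#' tie-break), CV accuracy and empirical p.
#'
#' @param coh two-group [cohort()].
#' @param subclusters list from [split_clusters_by_atlas()].
#' @param amap the `accuracy_map` the clusters came from (peak lookup).
#' @param config a [permutation_config()].
#' @param n_folds,variance_retained,cost,fold_seed CV protocol parameters.
#' @return data frame with one row per sub-cluster: `subcluster_id`,
#'   `cluster_id`, `label`, `region`, `unlabeled`, `x`, `y`, `z`, `size`,
#'   `accuracy`, `perm_p`.
#' @export
score_subclusters <- function(coh, subclusters, amap,
                              config = permutation_config(),
                              n_folds = 5L, variance_retained = 0.8,
                              cost = 1, fold_seed = 1L) {
  sub_seeds <- derive_seeds(config$seed, max(length(subclusters), 1L))
  rows <- lapply(seq_along(subclusters), function(i) {
    sc <- subclusters[[i]]
    pt <- permutation_test(
      coh, sc$voxels,
      permutation_config(config$k, config$p_threshold, config$min_size,
                         seed = sub_seeds[i]),
      n_folds, variance_retained, cost, fold_seed)
    vals <- amap$accuracy$data[sc$voxels]
    pk <- peak_voxel(sc$voxels, vals)
    mm <- as.numeric(voxel_to_world(amap$accuracy, sc$voxels[pk, ]))
    data.frame(subcluster_id = i, cluster_id = sc$parent, label = sc$label,
               region = sc$region, unlabeled = sc$unlabeled,
               x = mm[1], y = mm[2], z = mm[3], size = sc$size,
               accuracy = pt$observed, perm_p = pt$p,
               stringsAsFactors = FALSE)
  })
  if (length(rows)) do.call(rbind, rows) else
    data.frame(subcluster_id = integer(), cluster_id = integer(),
               label = integer(), region = character(), unlabeled = logical(),
               x = numeric(), y = numeric(), z = numeric(), size = integer(),
               accuracy = numeric(), perm_p = numeric())
}

#' Select biomarker sub-clusters
#'
#' Keeps sub-clusters with `perm_p <= p_threshold` and
#' `size >= min_size` (p <= 0.01 and extent >= 50 voxels by default) — the
#' selection rule that turns stable discriminative sub-clusters into the
#' reported neuroimaging biomarkers.  Background-label sub-clusters are
#' excluded by default since the motivation of the grouped analysis is
#' respecting anatomical boundaries.
#'
#' @param scored data frame from [score_subclusters()].
#' @param subclusters the matching list from [split_clusters_by_atlas()].
#' @param dim grid dimensions for the output mask.
#' @param p_threshold,min_size selection thresholds (defaults 0.01, 50).
#' @param include_unlabeled keep background sub-clusters too (default
#'   `FALSE`).
#' @return list with `mask` (logical 3D array, union of selected voxels) and
#'   `report` (rows of `scored` that pass, sorted by cluster id, with
#'   accuracy as `acc_pct`).
#' @export
select_biomarkers <- function(scored, subclusters, dim,
                              p_threshold = 0.01, min_size = 50L,
                              include_unlabeled = FALSE) {
  keep <- scored$perm_p <= p_threshold & scored$size >= min_size
  if (!include_unlabeled) keep <- keep & !scored$unlabeled
  mask <- array(FALSE, dim)
  for (i in scored$subcluster_id[keep]) {
    mask[subclusters[[i]]$voxels] <- TRUE
  }
  report <- scored[keep, , drop = FALSE]
  report <- report[order(report$cluster_id, report$subcluster_id), ,
                   drop = FALSE]
  report$acc_pct <- 100 * report$accuracy
  rownames(report) <- NULL
  list(mask = mask, report = report)
}

#' Model- plus feature-level biomarker discovery pipeline
#'
#' Convenience wrapper running the full identification chain for one
#' patients-versus-controls contrast: searchlight accuracy map, accuracy
#' thresholding with cluster-extent filtering, atlas splitting, sub-cluster
#' scoring with the permutation test, and biomarker selection.
#'
#' @param coh a three- or two-group [cohort()].
#' @param atl the parcellation [atlas()].
#' @param patient_group,control_group the contrasted labels (default ET vs
#'   NC).
#' @param sl_config a [searchlight_config()].
#' @param perm_config a [permutation_config()].
#' @return list with `accuracy_map`, `clusters`, `subclusters`, `scored`,
#'   `mask`, `report`.
#' @export
find_biomarkers <- function(coh, atl, patient_group = "ET",
                            control_group = "NC",
                            sl_config = searchlight_config(),
                            perm_config = permutation_config()) {
  two <- subset_cohort(coh, c(patient_group, control_group))
  amap <- searchlight_accuracy_map(two, sl_config)
  clusters <- threshold_accuracy_map(amap, sl_config)
  subclusters <- split_clusters_by_atlas(clusters, atl)
  scored <- score_subclusters(two, subclusters, amap, perm_config,
                              n_folds = sl_config$n_folds,
                              variance_retained = sl_config$variance_retained,
                              cost = sl_config$cost,
                              fold_seed = sl_config$seed)
  sel <- select_biomarkers(scored, subclusters, dim(coh$mask),
                           perm_config$p_threshold, perm_config$min_size)
  list(accuracy_map = amap, clusters = clusters, subclusters = subclusters,
       scored = scored, mask = sel$mask, report = sel$report)
}
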
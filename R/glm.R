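#' Voxelwise two-sample t-map with nuisance covariates
#'
#' Fits, at every mask voxel, an ordinary least-squares model of GM intensity
#' on `[intercept, group indicator, covariates]` for the subjects of two
#' groups, and returns the t-statistic of the group coefficient — the
#' group-comparison branch of the framework, in which age, sex and total
#' intracranial volume are regressed out during the two-sample test.  With no
#' covariates this reduces exactly to the classical pooled two-sample t.
#'
#' @param coh a [cohort()] containing both groups.
#' @param group_a,group_b group labels to contrast; the group indicator is 1
#'   for `group_a`, so positive t means `group_a > group_b`.
#' @param covariates character subset of `c("age", "sex", "tiv")` to regress
#'   out (default all three).
#' @return a `glm_result`: list with `tmap` (a [volume()], 0 outside the
#'   mask and at zero-variance voxels), `dof` (residual degrees of freedom,
#'   `n - rank(design)`), `group_a`, `group_b`, and `mask`.
#' @export
fit_glm_tmap <- function(coh, group_a, group_b,
                         covariates = c("age", "sex", "tiv")) {
  two <- subset_cohort(coh, c(group_a, group_b))
  n <- n_subjects(two)
  if (min(table(droplevels(two$groups))) < 2L) {
    stop("both groups need at least 2 subjects")
  }
  ind <- as.numeric(two$groups == group_a)
  X <- cbind(intercept = 1, group = ind)
  for (cv in covariates) X <- cbind(X, two$covariates[[cv]])
  colnames(X) <- c("intercept", "group", covariates)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; offending column(s): ",
         paste(dropped, collapse = ", "))
  }
  fm <- build_feature_matrix(two)
  Y <- fm$X                                  # n x V
  beta <- qr.coef(qrX, Y)                    # p x V
  res <- Y - X %*% beta
  dof <- n - ncol(X)
  sigma2 <- colSums(res^2) / dof
  xtx_inv_gg <- chol2inv(qr.R(qrX))[2L, 2L]
  se <- sqrt(sigma2 * xtx_inv_gg)
  t <- ifelse(se > 0, beta["group", ] / se, 0)
  # voxels constant across subjects carry no evidence: force t = 0 there
  cm <- colMeans(Y)
  var_y <- colSums(sweep(Y, 2L, cm)^2) / (n - 1)
  t[var_y <= 1e-12 * (1 + cm^2)] <- 0
  tmap <- features_to_volume(fm, t, dim(coh$mask), coh$affine)
  structure(list(tmap = tmap, dof = dof, group_a = group_a,
                 group_b = group_b, mask = two$mask),
            class = "glm_result")
}

#' @export
print.glm_result <- function(x, ...) {
  cat(sprintf("<glm_result> %s vs %s, dof = %d, |t| max = %.3f\n",
              x$group_a, x$group_b, x$dof, max(abs(x$tmap$data))))
  invisible(x)
}

#' Threshold a t-map into supra-threshold clusters
#'
#' Applies a one-tailed uncorrected voxel threshold in the requested contrast
#' direction (`"greater"` keeps voxels supporting `group_a > group_b`,
#' `"less"` the reverse) followed by cluster-extent filtering — the
#' significance rule p < 0.001 (uncorrected) with cluster size >= 50.
#'
#' @param result a `glm_result` from [fit_glm_tmap()].
#' @param direction `"greater"` or `"less"`.
#' @param p_threshold one-tailed uncorrected p threshold, in (0,1)
#'   (default 0.001).
#' @param min_cluster minimum cluster extent in voxels (default 50).
#' @param connectivity cluster connectivity (default 26).
#' @return a `cluster_set` (see [extract_clusters()]).
#' @export
threshold_tmap <- function(result, direction = c("greater", "less"),
                           p_threshold = 0.001, min_cluster = 50L,
                           connectivity = 26L) {
  direction <- match.arg(direction)
  if (p_threshold <= 0 || p_threshold >= 1) stop("p_threshold must be in (0,1)")
  tcrit <- stats::qt(1 - p_threshold, df = result$dof)
  supra <- if (direction == "greater") result$tmap$data > tcrit
           else result$tmap$data < -tcrit
  supra <- supra & result$mask
  extract_clusters(result$tmap, supra, min_size = min_cluster,
                   connectivity = connectivity)
}

#' Cluster report with atlas region names
#'
#' Formats a cluster set the way VBM group-comparison tables are reported:
#' one row per cluster with the contributing atlas regions (every label
#' overlapping the cluster, ordered by descending voxel count), Brodmann
#' annotations where the atlas provides them, the peak world coordinate, the
#' cluster extent and the peak statistic.
#'
#' @param clusters a `cluster_set`.
#' @param atl an [atlas()] on the same grid.
#' @param statistic_name column name for the peak statistic (default `"T"`).
#' @return data frame with columns `cluster_id`, `regions`, `ba`, `x`, `y`,
#'   `z`, `size` and the peak statistic.
#' @export
cluster_report <- function(clusters, atl, statistic_name = "T") {
  if (!identical(dim(atl$labels), clusters$dim)) {
    stop("atlas grid does not match cluster grid")
  }
  rows <- lapply(seq_along(clusters$clusters), function(i) {
    cl <- clusters$clusters[[i]]
    labs <- atl$labels[cl$voxels]
    cnt <- sort(table(labs), decreasing = TRUE)
    ord_labs <- as.integer(names(cnt))
    ba <- atl$table$ba[match(ord_labs, atl$table$label)]
    data.frame(cluster_id = i,
               regions = paste(region_name(atl, ord_labs), collapse = ","),
               ba = paste(unique(stats::na.omit(ba)), collapse = ","),
               x = cl$peak_mm[1], y = cl$peak_mm[2], z = cl$peak_mm[3],
               size = cl$size, stat = cl$peak_value,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster_id = integer(), regions = character(),
               ba = character(), x = numeric(), y = numeric(), z = numeric(),
               size = integer(), stat = numeric())
  names(out)[names(out) == "stat"] <- statistic_name
  out
}

#' Write a cluster or biomarker report as TSV
#'
#' @param report data frame from [cluster_report()] or
#'   [select_biomarkers()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
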
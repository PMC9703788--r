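#' Study cohorts of gray-matter volumes
#'
#' A `cohort` stacks per-subject 3D gray-matter maps that share one grid and
#' affine, together with the group label of each subject (NC, ET or PD),
#' nuisance covariates (age in years, sex as a 0/1 indicator, total
#' intracranial volume in ml) and an analysis mask.
#'
#' @param data 4D numeric array, `x * y * z * subject`.
#' @param groups character or factor of length `n_subjects` with values in
#'   `NC`, `ET`, `PD`.
#' @param covariates data frame with numeric columns `age`, `sex`, `tiv`
#'   (one row per subject; `tiv` must be positive).
#' @param mask logical 3D array on the same grid with at least one `TRUE`
#'   voxel.
#' @param affine 4x4 voxel-to-world transform shared by all volumes.
#' @return an object of class `cohort`.
#' @export
cohort <- function(data, groups, covariates, mask, affine = diag(4)) {
  if (length(dim(data)) != 4L) stop("cohort data must be a 4D array")
  n <- dim(data)[4]
  groups <- factor(as.character(groups), levels = c("NC", "ET", "PD"))
  if (anyNA(groups)) stop("groups must be NC, ET or PD")
  if (length(groups) != n) stop("groups length must match subject count")
  if (!all(c("age", "sex", "tiv") %in% names(covariates))) {
    stop("covariates must have columns age, sex, tiv")
  }
  if (nrow(covariates) != n) stop("covariates rows must match subject count")
  if (any(covariates$tiv <= 0)) stop("tiv must be positive")
  if (!identical(dim(mask), dim(data)[1:3])) {
    stop("mask grid must match volume grid")
  }
  if (!any(mask)) stop("mask must contain at least one voxel")
  structure(list(data = data, groups = groups,
                 covariates = as.data.frame(covariates),
                 mask = mask, affine = as.matrix(affine)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  tab <- table(droplevels(x$groups))
  cat(sprintf("<cohort> %s grid, %d subjects (%s), mask %d voxels\n",
              paste(dim(x$data)[1:3], collapse = "x"), dim(x$data)[4],
              paste(names(tab), tab, sep = "=", collapse = ", "),
              sum(x$mask)))
  invisible(x)
}

#' Number of subjects in a cohort
#' @param coh a [cohort()].
#' @return integer subject count.
#' @export
n_subjects <- function(coh) dim(coh$data)[4]

#' Extract one subject's map as a volume
#' @param coh a [cohort()].
#' @param i subject index.
#' @return a [volume()].
#' @export
subject_volume <- function(coh, i) {
  volume(coh$data[, , , i], coh$affine)
}

#' Restrict a cohort to selected groups
#'
#' @param coh a [cohort()].
#' @param groups character vector of group labels to keep.
#' @return a [cohort()] containing only those subjects, in original order.
#' @export
subset_cohort <- function(coh, groups) {
  keep <- which(coh$groups %in% groups)
  if (!length(keep)) stop("no subjects in groups: ", paste(groups, collapse = ", "))
  cohort(coh$data[, , , keep, drop = FALSE], as.character(coh$groups[keep]),
         coh$covariates[keep, , drop = FALSE], coh$mask, coh$affine)
}

#' Subjects-by-voxels feature matrix
#'
#' Flattens the masked voxels of every subject into one numeric matrix, the
#' input format of all classifier stages.  Columns follow the column-major
#' (x-fastest) order of the mask voxels and the voxel index of every column
#' is returned, so features always map back to locations.
#'
#' @param coh a [cohort()].
#' @param mask logical 3D array; defaults to the cohort's analysis mask.
#' @return list with `X` (`n_subjects x n_voxels` matrix) and `voxels`
#'   (`n_voxels x 3` integer index matrix).
#' @export
build_feature_matrix <- function(coh, mask = coh$mask) {
  if (!identical(dim(mask), dim(coh$data)[1:3])) {
    stop("mask grid must match cohort grid")
  }
  lin <- which(mask)
  if (!length(lin)) stop("mask is empty")
  n <- n_subjects(coh)
  nv <- prod(dim(coh$data)[1:3])
  flat <- matrix(coh$data, nrow = nv, ncol = n)
  list(X = t(flat[lin, , drop = FALSE]), voxels = arrayInd(lin, dim(mask)))
}

#' Rebuild a volume from one feature-matrix row
#'
#' Inverse of [build_feature_matrix()] for a single subject: masked voxels
#' receive the row's values, everything else is zero.
#'
#' @param features list returned by [build_feature_matrix()].
#' @param values numeric vector, one value per feature column.
#' @param dim grid dimensions.
#' @param affine 4x4 voxel-to-world transform.
#' @return a [volume()].
#' @export
features_to_volume <- function(features, values, dim, affine = diag(4)) {
  stopifnot(length(values) == nrow(features$voxels))
  a <- array(0, dim)
  a[features$voxels] <- values
  volume(a, affine)
}
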
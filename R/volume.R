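#' 3D scalar volumes with world-coordinate geometry
#'
#' A `volume` is the package's container for one 3D scalar image: a numeric
#' array plus a 4x4 affine mapping zero-based voxel indices to world
#' coordinates in millimetres (RAS+ convention, as in NIfTI-1).  Per-subject
#' smoothed gray-matter maps, t-maps, accuracy maps and masks are all volumes
#' on a shared grid.
#'
#' @param data numeric 3D array.
#' @param affine 4x4 numeric matrix, voxel-to-world transform (mm).  The
#'   default places the origin at voxel (1,1,1) with 1 mm isotropic voxels.
#' @return An object of class `volume` with fields `data` and `affine`.
#' @examples
#' v <- volume(array(0, c(4, 4, 4)), diag(c(2, 2, 2, 1)))
#' voxel_size(v)
#' @export
volume <- function(data, affine = diag(4)) {
  if (length(dim(data)) != 3L) {
    stop("volume data must be a 3D array, got ", length(dim(data)), " dimensions")
  }
  if (!all(is.finite(data))) {
    stop("volume data must be finite everywhere")
  }
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L))) {
    stop("affine must be a 4x4 matrix")
  }
  if (abs(det(affine)) < .Machine$double.eps) {
    stop("affine must be invertible")
  }
  structure(list(data = data, affine = affine), class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$data)
  vs <- voxel_size(x)
  cat(sprintf("<volume> %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], vs[1], vs[2], vs[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.volume <- function(x) dim(x$data)

#' Voxel dimensions of a volume
#'
#' Column norms of the affine's rotation/zoom block, in mm.
#'
#' @param vol a [volume()].
#' @return numeric length-3 vector of voxel edge lengths (mm).
#' @export
voxel_size <- function(vol) {
  sqrt(colSums(vol$affine[1:3, 1:3]^2))
}

#' Read a 3D NIfTI-1 image as a volume
#'
#' @param path path to a `.nii` or `.nii.gz` file holding a single 3D frame.
#' @return a [volume()] carrying the file's data and affine (sform/qform as
#'   resolved by RNifti, RAS+ world coordinates).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- img[, , , 1L]
    d <- dim(img)
  }
  if (length(d) != 3L) {
    stop("expected a 3D single-frame NIfTI image, got ",
         length(d), "D data in ", path)
  }
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = dim(aff))
  volume(array(as.numeric(img), dim = d), aff)
}

#' Write a volume to NIfTI-1
#'
#' @param vol a [volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- voxel_size(vol)
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Map voxel indices to world coordinates
#'
#' Applies the volume's affine to 1-based voxel indices (the R array
#' convention; the affine itself acts on zero-based indices per NIfTI).
#'
#' @param vol a [volume()].
#' @param index integer vector of length 3, or an n x 3 matrix of indices.
#' @return world coordinates in mm: length-3 vector or n x 3 matrix.
#' @export
voxel_to_world <- function(vol, index) {
  idx <- if (is.matrix(index)) index else matrix(index, nrow = 1L)
  d <- dim(vol$data)
  if (any(idx < 1L) || any(sweep(idx, 2L, d, ">"))) {
    stop("voxel index out of bounds for grid ", paste(d, collapse = "x"))
  }
  hom <- cbind(idx - 1, 1)
  out <- hom %*% t(vol$affine)
  out <- out[, 1:3, drop = !is.matrix(index)]
  out
}

#' Map world coordinates to voxel indices
#'
#' Inverse of [voxel_to_world()]; returns fractional (unrounded) 1-based
#' indices so that the round trip is exact.
#'
#' @param vol a [volume()].
#' @param world numeric length-3 vector or n x 3 matrix of mm coordinates.
#' @return fractional voxel indices, same shape convention as the input.
#' @export
world_to_voxel <- function(vol, world) {
  w <- if (is.matrix(world)) world else matrix(world, nrow = 1L)
  hom <- cbind(w, 1)
  out <- hom %*% t(solve(vol$affine))
  out <- out[, 1:3, drop = !is.matrix(world)] + 1
  out
}

#' Gaussian smoothing of a volume
#'
#' Separable Gaussian filter parameterised by full width at half maximum, the
#' smoothing convention of voxel-based morphometry pipelines.  The per-axis
#' kernel standard deviation is `fwhm / (sqrt(8 * log(2)) * voxel_size)`
#' voxels; kernels are truncated at 4 standard deviations and renormalised to
#' unit sum, and boundaries use reflect padding (edge voxel repeated), so the
#' filter preserves constants and conserves total intensity for interior
#' compact inputs.
#'
#' @param vol a [volume()].
#' @param fwhm full width at half maximum in mm; `0` returns the input
#'   unchanged.
#' @return smoothed [volume()] on the same grid.
#' @export
gaussian_smooth <- function(vol, fwhm) {
  if (fwhm < 0) stop("fwhm must be non-negative, got ", fwhm)
  if (fwhm == 0) return(vol)
  vs <- voxel_size(vol)
  sigma_vox <- fwhm_to_sigma(fwhm) / vs
  out <- vol$data
  for (axis in 1:3) {
    kern <- gaussian_kernel_1d(sigma_vox[axis])
    if (length(kern) > 1L) out <- convolve_axis(out, kern, axis)
  }
  volume(out, vol$affine)
}

#' Convert FWHM to Gaussian sigma
#'
#' @param fwhm full width at half maximum (any length unit).
#' @return `fwhm / sqrt(8 * log(2))`, the standard deviation in the same unit.
#' @export
fwhm_to_sigma <- function(fwhm) {
  fwhm / sqrt(8 * log(2))
}

gaussian_kernel_1d <- function(sigma_vox) {
  r <- ceiling(4 * sigma_vox)
  x <- seq(-r, r)
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# Reflect out-of-range 1-based index into [1, n] (edge repeated).
reflect_index <- function(i, n) {
  j <- (i - 1) %% (2L * n)
  j <- ifelse(j < 0, j + 2L * n, j)
  ifelse(j >= n, 2L * n - 1L - j, j) + 1L
}

# 1D convolution along one axis of a 3D array via a banded matrix multiply.
convolve_axis <- function(arr, kern, axis) {
  d <- dim(arr)
  perm <- switch(axis, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  a <- if (axis == 1L) arr else aperm(arr, perm)
  da <- dim(a)
  n <- da[1]
  r <- (length(kern) - 1L) %/% 2L
  K <- matrix(0, n, n)
  for (off in seq(-r, r)) {
    src <- reflect_index(seq_len(n) + off, n)
    K[cbind(seq_len(n), src)] <- K[cbind(seq_len(n), src)] + kern[off + r + 1L]
  }
  dim(a) <- c(n, prod(da[-1]))
  out <- K %*% a
  dim(out) <- da
  if (axis == 1L) out else aperm(out, order(perm))
}
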
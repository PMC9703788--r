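#' Connected-component cluster extraction
#'
#' Decomposes the `TRUE` voxels of a mask into connected components under
#' 6-, 18- or 26-connectivity and discards components smaller than a minimum
#' extent — the cluster-extent thresholding step used both for the t-map
#' branch and for accuracy-map thresholding.  Each surviving cluster records
#' its voxels, size, and the peak voxel: the voxel of maximal `|statmap|`
#' within the component, ties broken by the lexicographically smallest
#' (x, y, z) index so reports are deterministic.
#'
#' @param statmap a [volume()] supplying the statistic used for peak
#'   localisation (t, accuracy, ...).
#' @param mask logical 3D array on the same grid; `TRUE` marks
#'   supra-threshold voxels.
#' @param min_size minimum cluster extent in voxels (clusters with
#'   `size >= min_size` are kept; default 50).
#' @param connectivity one of 6 (faces), 18 (faces+edges), 26
#'   (faces+edges+corners, the default).
#' @return a `cluster_set`: list with `clusters` (each holding `voxels`
#'   (n x 3 integer matrix), `size`, `peak_voxel`, `peak_mm`, `peak_value`),
#'   plus `connectivity`, `dim` and `affine`.  An empty mask yields zero
#'   clusters.
#' @export
extract_clusters <- function(statmap, mask, min_size = 50L, connectivity = 26L) {
  stopifnot(is.logical(mask))
  if (!identical(dim(statmap$data), dim(mask))) {
    stop("statmap and mask must share the same grid")
  }
  connectivity <- match.arg(as.character(connectivity), c("6", "18", "26"))
  connectivity <- as.integer(connectivity)

  labels <- label_components(mask, connectivity)
  clusters <- list()
  if (labels$n > 0L) {
    for (lab in seq_len(labels$n)) {
      vox <- labels$coords[labels$labels == lab, , drop = FALSE]
      if (nrow(vox) < min_size) next
      vals <- statmap$data[vox]
      pk <- peak_voxel(vox, vals)
      clusters[[length(clusters) + 1L]] <- list(
        voxels = vox,
        size = nrow(vox),
        peak_voxel = vox[pk, ],
        peak_mm = as.numeric(voxel_to_world(statmap, vox[pk, ])),
        peak_value = vals[pk]
      )
    }
  }
  # order clusters by decreasing size, ties by peak voxel order
  if (length(clusters) > 1L) {
    ord <- order(-vapply(clusters, `[[`, 0L, "size"))
    clusters <- clusters[ord]
  }
  structure(list(clusters = clusters,
                 connectivity = connectivity,
                 dim = dim(mask),
                 affine = statmap$affine),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d cluster(s), %d-connectivity\n",
              length(x$clusters), x$connectivity))
  for (i in seq_along(x$clusters)) {
    cl <- x$clusters[[i]]
    cat(sprintf("  %d: %d voxels, peak %.4g at (%.1f, %.1f, %.1f) mm\n",
                i, cl$size, cl$peak_value,
                cl$peak_mm[1], cl$peak_mm[2], cl$peak_mm[3]))
  }
  invisible(x)
}

#' Union of cluster voxels as a logical mask
#'
#' @param clusters a `cluster_set` from [extract_clusters()].
#' @return logical 3D array, `TRUE` on every voxel of every cluster.
#' @export
cluster_mask <- function(clusters) {
  m <- array(FALSE, clusters$dim)
  for (cl in clusters$clusters) m[cl$voxels] <- TRUE
  m
}

# Index (row) of the peak: max |value|, lexicographic (x,y,z) tie-break.
peak_voxel <- function(vox, vals) {
  order(-abs(vals), vox[, 1], vox[, 2], vox[, 3])[1L]
}

# Neighbor offsets for a connectivity class: Manhattan radius 1 (6),
# Chebyshev 1 excluding corners (18), full Chebyshev 1 (26).
neighbor_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  r <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = r == 1,
                 "18" = r >= 1 & r <= 2,
                 "26" = r >= 1)
  g[keep, , drop = FALSE]
}

# Flood-fill labelling of TRUE voxels. Returns coords (m x 3), labels (m),
# and component count n.
label_components <- function(mask, connectivity) {
  d <- dim(mask)
  lin <- which(mask)
  m <- length(lin)
  if (m == 0L) {
    return(list(coords = matrix(integer(), 0L, 3L), labels = integer(), n = 0L))
  }
  coords <- arrayInd(lin, d)
  row_of <- integer(prod(d))
  row_of[lin] <- seq_len(m)
  offs <- neighbor_offsets(connectivity)
  s1 <- 1L
  s2 <- d[1]
  s3 <- d[1] * d[2]
  labels <- integer(m)
  cur <- 0L
  stack <- integer(m)
  for (start in seq_len(m)) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    labels[start] <- cur
    stack[1L] <- start
    top <- 1L
    while (top > 0L) {
      i <- stack[top]
      top <- top - 1L
      x <- coords[i, 1]; y <- coords[i, 2]; z <- coords[i, 3]
      nx <- offs[, 1] + x; ny <- offs[, 2] + y; nz <- offs[, 3] + z
      ok <- nx >= 1L & nx <= d[1] & ny >= 1L & ny <= d[2] & nz >= 1L & nz <= d[3]
      if (!any(ok)) next
      nl <- (nx[ok] - 1L) * s1 + (ny[ok] - 1L) * s2 + (nz[ok] - 1L) * s3 + 1L
      nb <- row_of[nl]
      nb <- nb[nb > 0L]
      nb <- nb[labels[nb] == 0L]
      if (length(nb)) {
        labels[nb] <- cur
        stack[(top + 1L):(top + length(nb))] <- nb
        top <- top + length(nb)
      }
    }
  }
  list(coords = coords, labels = labels, n = cur)
}
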
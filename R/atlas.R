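#' Labelled parcellation atlases
#'
#' An `atlas` pairs an integer-labelled 3D grid (0 = background) with a label
#' table mapping each label to a region name and an optional Brodmann-area
#' annotation, in the style of the AAL parcellation.  The feature-level stage
#' uses it to split searchlight clusters along anatomical boundaries.
#'
#' @param labels integer 3D array of parcel labels; 0 is background.
#' @param table data frame with columns `label`, `name` and optionally `ba`;
#'   every nonzero label present in the grid must appear in it.
#' @param affine 4x4 voxel-to-world transform shared with the study grid.
#' @return an object of class `atlas`.
#' @export
atlas <- function(labels, table, affine = diag(4)) {
  if (length(dim(labels)) != 3L) stop("atlas labels must be a 3D array")
  storage.mode(labels) <- "integer"
  if (any(labels < 0L)) stop("atlas labels must be nonnegative integers")
  if (!all(c("label", "name") %in% names(table))) {
    stop("atlas table needs columns 'label' and 'name'")
  }
  if (is.null(table$ba)) table$ba <- NA_character_
  present <- setdiff(sort(unique(as.integer(labels))), 0L)
  missing <- setdiff(present, table$label)
  if (length(missing)) {
    stop("labels present in grid but absent from table: ",
         paste(missing, collapse = ", "))
  }
  structure(list(labels = labels, table = table, affine = as.matrix(affine)),
            class = "atlas")
}

#' @export
print.atlas <- function(x, ...) {
  n <- sum(x$table$label %in% unique(as.integer(x$labels)))
  cat(sprintf("<atlas> %s grid, %d parcel(s), %d foreground voxels\n",
              paste(dim(x$labels), collapse = "x"), n, sum(x$labels > 0L)))
  invisible(x)
}

#' Region name(s) for atlas label(s)
#'
#' @param atl an [atlas()].
#' @param label integer label vector; 0 maps to `"unlabeled"`.
#' @return character vector of region names.
#' @export
region_name <- function(atl, label) {
  out <- atl$table$name[match(label, atl$table$label)]
  out[label == 0L] <- "unlabeled"
  out
}

#' Read an atlas from NIfTI labels plus a TSV label table
#'
#' The table is tab-separated with columns `label`, `name` and optional `ba`,
#' no quoting.
#'
#' @param label_path NIfTI file of integer labels.
#' @param table_path TSV label table.
#' @return an [atlas()].
#' @export
read_atlas <- function(label_path, table_path) {
  vol <- read_volume(label_path)
  tab <- utils::read.delim(table_path, stringsAsFactors = FALSE)
  lab <- round(vol$data)
  storage.mode(lab) <- "integer"
  atlas(lab, tab, vol$affine)
}

#' Write an atlas to NIfTI + TSV
#'
#' @param atl an [atlas()].
#' @param label_path output NIfTI path.
#' @param table_path output TSV path.
#' @return invisibly, a character vector of the two paths.
#' @export
write_atlas <- function(atl, label_path, table_path) {
  write_volume(volume(array(as.numeric(atl$labels), dim(atl$labels)),
                      atl$affine), label_path)
  utils::write.table(atl$table, table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(label_path, table_path))
}
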
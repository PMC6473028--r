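#' Read a subject x ROI signal table
#'
#' Reads a delimited (comma or tab, sniffed) table with one row per subject:
#' metadata columns `subject_id`, `group`, `age`, `sex`, then one numeric
#' column per atlas region. Columns are reordered to atlas order when they
#' arrive permuted; a ROI with zero variance within any group is flagged with
#' a warning and recorded in the `zero_variance` attribute.
#'
#' @param path Path to the delimited file.
#' @param atlas Atlas definition tibble (default bundled 90-region atlas).
#' @return A tibble: `subject_id`, `group`, `age`, `sex`, then ROI columns in
#'   atlas order.
#' @export
read_roi_table <- function(path, atlas = aal90_atlas()) {
  df <- read_delimited(path)
  validate_roi_table(as_tibble(df), atlas)
}

#' Validate (and reorder) a subject x ROI table against an atlas
#'
#' @param table Data frame with metadata and ROI columns.
#' @param atlas Atlas definition tibble.
#' @return The validated tibble with ROI columns in atlas order.
#' @export
validate_roi_table <- function(table, atlas = aal90_atlas()) {
  table <- as_tibble(table)
  missing_meta <- setdiff(META_COLS, names(table))
  if (length(missing_meta) > 0) {
    abort(paste0("Subject table lacks covariate/metadata column(s): ",
                 paste(missing_meta, collapse = ", ")))
  }
  missing_roi <- setdiff(atlas$abbrev, names(table))
  if (length(missing_roi) > 0) {
    abort(paste0("Subject table lacks ROI column(s): ",
                 paste(head(missing_roi, 5), collapse = ", "),
                 if (length(missing_roi) > 5) ", ..." else ""))
  }
  table <- table[, c(META_COLS, atlas$abbrev)]
  sig <- as.data.frame(table)[, atlas$abbrev, drop = FALSE]
  non_num <- names(sig)[!vapply(sig, is.numeric, logical(1))]
  if (length(non_num) > 0) {
    abort(paste0("Non-numeric ROI signal column(s): ",
                 paste(non_num, collapse = ", ")))
  }
  if (anyNA(sig)) {
    abort("Missing values in ROI signal columns are not allowed.")
  }
  flagged <- character(0)
  for (g in unique(table$group)) {
    sub <- sig[table$group == g, , drop = FALSE]
    if (nrow(sub) > 1) {
      v <- vapply(sub, stats::var, numeric(1))
      flagged <- union(flagged, names(v)[v == 0])
    }
  }
  if (length(flagged) > 0) {
    warn(paste0("ROI(s) with zero variance within a group: ",
                paste(flagged, collapse = ", ")))
  }
  attr(table, "zero_variance") <- flagged
  table
}

#' Write a subject x ROI table as CSV
#'
#' @param table Subject table (see [read_roi_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roi_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract per-ROI mean intensities from a labelled volume
#'
#' Averages the image intensity over each atlas region of an integer-labelled
#' parcellation volume (voxels labelled 0 are background and ignored), e.g.
#' ROI mean uptake from a spatially normalized PET volume and an AAL-style
#' label image.
#'
#' @param image 3-D numeric array or path to a NIfTI-1 volume.
#' @param labels 3-D integer array or path to a NIfTI-1 label volume on the
#'   same grid.
#' @param atlas Atlas definition tibble; every `roi_id` must occur in
#'   `labels`.
#' @return Named numeric vector of ROI means, in atlas order.
#' @export
extract_roi_means <- function(image, labels, atlas = aal90_atlas()) {
  image <- as_volume(image)
  labels <- as_volume(labels)
  if (!identical(dim(image), dim(labels))) {
    abort(sprintf("Image and label grids differ: %s vs %s.",
                  paste(dim(image), collapse = "x"),
                  paste(dim(labels), collapse = "x")))
  }
  lab <- as.integer(round(labels))
  present <- unique(lab)
  missing <- setdiff(atlas$roi_id, present)
  if (length(missing) > 0) {
    abort(paste0("Label volume lacks atlas roi_id(s): ",
                 paste(missing, collapse = ", ")))
  }
  sums <- vapply(atlas$roi_id, function(id) sum(image[lab == id]), numeric(1))
  counts <- vapply(atlas$roi_id, function(id) sum(lab == id), numeric(1))
  means <- sums / counts
  names(means) <- atlas$abbrev
  means
}

as_volume <- function(x) {
  if (is.character(x)) {
    x <- RNifti::readNifti(x)
  }
  arr <- as.array(x)
  if (length(dim(arr)) != 3) {
    abort("Expected a 3-D volume.")
  }
  arr
}
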
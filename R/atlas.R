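#' The bundled 90-region AAL-style atlas
#'
#' Ninety cerebral regions (cerebellum excluded) in the conventional AAL
#' ordering: homotopic left/right pairs interleaved, left on odd ids, right on
#' even ids. Abbreviations carry a `.L`/`.R` suffix encoding the hemisphere.
#'
#' @return A tibble with columns `roi_id`, `abbrev`, `name`, `hemisphere`.
#' @examples
#' atlas <- aal90_atlas()
#' table(atlas$hemisphere)
#' @export
aal90_atlas <- function() {
  path <- system.file("extdata", "aal90_atlas.tsv", package = "metabnet",
                      mustWork = TRUE)
  load_atlas(path)
}

#' Load and validate an atlas definition table
#'
#' Reads a delimited (tab or comma, sniffed) table of ROI definitions with
#' columns `roi_id`, `abbrev` and optionally `name` and `hemisphere`. When no
#' `hemisphere` column is present it is parsed from a `.L`/`.R` suffix on the
#' abbreviation.
#'
#' @param path Path to a delimited text file.
#' @return A validated tibble with columns `roi_id`, `abbrev`, `name`,
#'   `hemisphere`.
#' @export
load_atlas <- function(path) {
  df <- read_delimited(path)
  required <- c("roi_id", "abbrev")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(paste0("Atlas file lacks required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!("name" %in% names(df))) df$name <- df$abbrev
  if (!("hemisphere" %in% names(df))) {
    suffix <- sub("^.*\\.", "", df$abbrev)
    df$hemisphere <- suffix
  }
  atlas <- tibble(
    roi_id = as.integer(df$roi_id),
    abbrev = as.character(df$abbrev),
    name = as.character(df$name),
    hemisphere = as.character(df$hemisphere)
  )
  validate_atlas(atlas)
  atlas
}

validate_atlas <- function(atlas) {
  if (any(is.na(atlas$roi_id)) || any(atlas$roi_id <= 0)) {
    abort("Atlas roi_id values must be positive integers.")
  }
  dup <- atlas$roi_id[duplicated(atlas$roi_id)]
  if (length(dup) > 0) {
    rows <- which(atlas$roi_id %in% dup)
    abort(sprintf("Duplicate atlas roi_id(s): %s (rows %s).",
                  paste(unique(dup), collapse = ", "),
                  paste(rows, collapse = ", ")))
  }
  dup_ab <- atlas$abbrev[duplicated(atlas$abbrev)]
  if (length(dup_ab) > 0) {
    abort(sprintf("Duplicate atlas abbreviation(s): %s.",
                  paste(unique(dup_ab), collapse = ", ")))
  }
  bad <- which(!(atlas$hemisphere %in% c("L", "R")))
  if (length(bad) > 0) {
    abort(sprintf(
      "Unknown hemisphere code(s) %s at row(s) %s; expected 'L' or 'R'.",
      paste(unique(atlas$hemisphere[bad]), collapse = ", "),
      paste(bad, collapse = ", ")))
  }
  invisible(atlas)
}

# Sniff the delimiter (tab vs comma) from the header line.
read_delimited <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "")
}
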
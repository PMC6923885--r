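# Feature table and cohort manifest I/O.
#
# A feature table is a data.frame with a `subject_id` column, numeric
# feature columns in a deterministic documented order, and optionally a
# `subtype` label column (last). CSV round-trips preserve values to full
# double precision.

#' Write a feature table to CSV
#'
#' @param table Data frame with `subject_id`, numeric feature columns and
#'   optionally a `subtype` column.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  if (anyDuplicated(names(table)))
    stop("format error: duplicate column names in feature table")
  out <- as.data.frame(table)
  num <- vapply(out, is.numeric, logical(1L))
  # %.17g guarantees lossless double round-trip through text
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  data.table::fwrite(out, path, quote = TRUE)
  invisible(path)
}

#' Read a feature table from CSV
#'
#' @param path CSV path written by [write_feature_table()].
#' @return Data frame; numeric feature columns restored as doubles.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  hdr <- names(data.table::fread(path, nrows = 0L, header = TRUE))
  if (anyDuplicated(hdr))
    stop("format error: duplicate column names in ", path)
  dt <- data.table::fread(path, header = TRUE, colClasses = list(
    character = intersect(c("subject_id", "subtype"), hdr)))
  df <- as.data.frame(dt)
  for (nm in setdiff(names(df), c("subject_id", "subtype"))) {
    df[[nm]] <- as.numeric(df[[nm]])
  }
  df
}

#' Names of the feature columns of a table
#'
#' @param table A feature table.
#' @return Character vector excluding the `subject_id`/`subtype` bookkeeping columns.
#' @export
feature_columns <- function(table) {
  setdiff(names(table), c("subject_id", "subtype"))
}

#' Read a cohort manifest
#'
#' The manifest is a CSV with columns `subject_id, t1, t1gd, t2, flair,
#' mask, subtype` (file paths relative to the manifest's directory or
#' absolute; `subtype` may be empty for unlabeled subjects). Row order is
#' preserved in all downstream outputs.
#'
#' @param path Manifest CSV path.
#' @return Data frame of the manifest with paths resolved.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("I/O error: no such manifest: ", path)
  m <- as.data.frame(data.table::fread(path, header = TRUE, colClasses = "character"))
  need <- c("subject_id", "t1", "t1gd", "t2", "flair", "mask")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop("format error: manifest missing column(s): ", paste(miss, collapse = ", "))
  if (!"subtype" %in% names(m)) m$subtype <- NA_character_
  m$subtype[m$subtype == ""] <- NA_character_
  base <- dirname(normalizePath(path))
  for (col in c("t1", "t1gd", "t2", "flair", "mask")) {
    rel <- !grepl("^(/|[A-Za-z]:)", m[[col]])
    m[[col]][rel] <- file.path(base, m[[col]][rel])
  }
  m
}

#' Load one subject from a manifest row
#'
#' Reads the four channel volumes and the segmentation mask, validating
#' co-registration (identical shape and spacing) and the label codes
#' {0, 1, 2, 4}.
#'
#' @param row One row of a [read_manifest()] data frame (or an equivalent
#'   named list with fields `subject_id`, `t1`, `t1gd`, `t2`, `flair`,
#'   `mask`, optionally `subtype`).
#' @return A [subject_record()].
#' @export
read_subject <- function(row) {
  paths <- c(T1 = row$t1, T1GD = row$t1gd, T2 = row$t2, FLAIR = row$flair)
  chans <- lapply(paths, read_nifti)
  study <- mpmri_study(row$subject_id, chans)
  mg <- read_nifti(row$mask)
  if (!same_grid(study$channels[[1L]], mg))
    stop("registration error: mask not on the channel grid for subject ",
         row$subject_id)
  mask <- segmentation_mask(array(as.integer(round(mg$values)), dim(mg$values)),
                            spacing = mg$spacing)
  subtype <- if (!is.null(row$subtype)) row$subtype else NA_character_
  subject_record(row$subject_id, study, mask, subtype = subtype)
}

#' Extract subject TC masks and labels from a cohort
#'
#' @param cohort List of [subject_record()]s.
#' @return Named list with `tc_masks` (list of logical arrays keyed by
#'   subject id) and `subtypes` (named character vector).
#' @export
cohort_tc_masks <- function(cohort) {
  ids <- vapply(cohort, function(s) s$subject_id, character(1L))
  tc <- lapply(cohort, function(s) region_mask(s$mask, "TC"))
  names(tc) <- ids
  st <- vapply(cohort, function(s) s$subtype, character(1L))
  names(st) <- ids
  list(tc_masks = tc, subtypes = st)
}
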
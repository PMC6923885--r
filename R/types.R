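#' Canonical subtype order
#'
#' The four transcriptomic glioblastoma subtypes in the fixed canonical
#' order used everywhere for keying, reporting and deterministic
#' tie-breaking.
#'
#' @return Character vector `c("classical", "mesenchymal", "proneural", "neural")`.
#' @export
subtype_levels <- function() {
  c("classical", "mesenchymal", "proneural", "neural")
}

#' MRI channel names
#'
#' The four co-registered structural channels, in fixed order.
#'
#' @return Character vector `c("T1", "T1GD", "T2", "FLAIR")`.
#' @export
channel_names <- function() {
  c("T1", "T1GD", "T2", "FLAIR")
}

# Segmentation label codes (BraTS convention).
LBL_NET <- 1L
LBL_ED  <- 2L
LBL_ET  <- 4L

#' Lobe/region names of the 9-region parcellation
#'
#' @return Character vector of the nine anatomical region names, whose
#'   position equals the integer code used in the parcellation volume.
#' @export
lobe_names <- function() {
  c("temporal", "frontal", "parietal", "occipital", "basal_ganglia",
    "cc_fornix", "insula", "cerebellum", "brain_stem")
}

#' Construct a voxel grid
#'
#' A `volume_grid` is a 3D numeric array plus per-axis voxel spacing in mm.
#' Axis order is (x, y, z) with z the axial stack direction; voxel indices
#' are 1-based in R, and all physical measurements multiply by `spacing`.
#'
#' @param values 3D numeric array.
#' @param spacing Numeric length-3, voxel size in mm per axis; strictly positive.
#' @return A `volume_grid` object.
#' @export
volume_grid <- function(values, spacing = c(1, 1, 1)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("volume_grid: `values` must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("volume_grid: spacing must be 3 strictly positive finite numbers")
  if (any(!is.finite(values)))
    stop("volume_grid: all values must be finite")
  structure(list(values = values, spacing = spacing), class = "volume_grid")
}

#' @export
dim.volume_grid <- function(x) dim(x$values)

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid %s, spacing %s mm>\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = "x")))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing - b$spacing) < tol)
}

#' Construct a multi-parametric MRI study
#'
#' @param subject_id Subject identifier string.
#' @param channels Named list of exactly four [volume_grid()]s keyed
#'   `T1`, `T1GD`, `T2`, `FLAIR`, all on one grid.
#' @return An `mpmri_study` object.
#' @export
mpmri_study <- function(subject_id, channels) {
  need <- channel_names()
  if (!setequal(names(channels), need))
    stop("registration error: channels must be exactly ", paste(need, collapse = ", "))
  channels <- channels[need]
  ref <- channels[[1L]]
  for (nm in need[-1L]) {
    if (!same_grid(ref, channels[[nm]]))
      stop("registration error: channel ", nm, " not on the common grid")
  }
  structure(list(subject_id = as.character(subject_id), channels = channels),
            class = "mpmri_study")
}

#' Construct a segmentation mask
#'
#' Integer label volume with the BraTS codes 0 = background, 1 = NET,
#' 2 = ED, 4 = ET. Tumor core (TC) is NET together with ET; whole tumor
#' (WT) is TC together with ED.
#'
#' @param labels 3D integer array.
#' @param spacing Voxel spacing in mm.
#' @return A `segmentation_mask` object.
#' @export
segmentation_mask <- function(labels, spacing = c(1, 1, 1)) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("mask error: labels must be a 3D array")
  lab <- as.integer(labels)
  bad <- setdiff(unique(lab), c(0L, LBL_NET, LBL_ED, LBL_ET))
  if (length(bad))
    stop("mask error: unknown label code(s) ", paste(bad, collapse = ", "))
  storage.mode(labels) <- "integer"
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("mask error: spacing must be 3 positive numbers")
  structure(list(labels = labels, spacing = spacing),
            class = "segmentation_mask")
}

#' Logical mask of one derived or primary tumor region
#'
#' @param mask A [segmentation_mask()].
#' @param region One of `"ED"`, `"ET"`, `"NET"`, `"TC"`, `"WT"`.
#' @return Logical 3D array.
#' @export
region_mask <- function(mask, region) {
  lab <- mask$labels
  switch(region,
    ED  = lab == LBL_ED,
    ET  = lab == LBL_ET,
    NET = lab == LBL_NET,
    TC  = lab == LBL_NET | lab == LBL_ET,
    WT  = lab != 0L,
    stop("unknown region: ", region))
}

#' Construct an anatomy context
#'
#' Brain mask, ventricle mask, and a 9-region lobe parcellation on the
#' shared cohort grid. Lobe codes partition the brain: every brain voxel
#' carries exactly one code in 1..9 (see [lobe_names()]); ventricles lie
#' inside the brain.
#'
#' @param brain_mask,ventricle_mask Logical 3D arrays.
#' @param lobe_parcellation Integer 3D array with codes 0 (outside brain) and 1..9.
#' @param spacing Voxel spacing in mm.
#' @return An `anatomy_context` object.
#' @export
anatomy_context <- function(brain_mask, ventricle_mask, lobe_parcellation,
                            spacing = c(1, 1, 1)) {
  brain_mask <- brain_mask != 0
  ventricle_mask <- ventricle_mask != 0
  storage.mode(lobe_parcellation) <- "integer"
  if (!identical(dim(brain_mask), dim(ventricle_mask)) ||
      !identical(dim(brain_mask), dim(lobe_parcellation)))
    stop("registration error: anatomy volumes not on one grid")
  if (any(ventricle_mask & !brain_mask))
    stop("anatomy error: ventricle voxels outside brain mask")
  if (any((lobe_parcellation != 0L) != brain_mask))
    stop("anatomy error: lobe codes must partition exactly the brain voxels")
  if (any(!lobe_parcellation %in% 0:9))
    stop("anatomy error: lobe codes must be 0..9")
  structure(list(brain_mask = brain_mask, ventricle_mask = ventricle_mask,
                 lobe_parcellation = lobe_parcellation,
                 spacing = as.numeric(spacing)),
            class = "anatomy_context")
}

#' Construct a subject record
#'
#' @param subject_id Identifier string.
#' @param study An [mpmri_study()].
#' @param mask A [segmentation_mask()] on the same grid.
#' @param subtype A subtype label from [subtype_levels()], or `NA` for
#'   unlabeled subjects at prediction time.
#' @return A `subject_record` object.
#' @export
subject_record <- function(subject_id, study, mask, subtype = NA_character_) {
  g <- study$channels[[1L]]
  if (!identical(dim(g$values), dim(mask$labels)) ||
      any(abs(g$spacing - mask$spacing) > 1e-6))
    stop("registration error: study and mask do not share one grid")
  if (!is.na(subtype) && !subtype %in% subtype_levels())
    stop("unknown subtype label: ", subtype)
  structure(list(subject_id = as.character(subject_id), study = study,
                 mask = mask, subtype = subtype),
            class = "subject_record")
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("<subject %s, grid %s, subtype %s>\n", x$subject_id,
              paste(dim(x$mask$labels), collapse = "x"),
              ifelse(is.na(x$subtype), "(unlabeled)", x$subtype)))
  invisible(x)
}
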
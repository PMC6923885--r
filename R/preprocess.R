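# Intensity normalization by histogram matching to a reference subject —
# the one in-scope preprocessing stage (inputs are assumed already
# denoised, bias-corrected, co-registered and skull-stripped).

#' Histogram-match one volume to a reference
#'
#' Monotone quantile mapping of the moving image's within-brain intensity
#' distribution onto the reference's, using `n_quantiles` equally spaced
#' quantile landmarks and linear interpolation between them. Voxels
#' outside the brain mask pass through unchanged; outputs are clamped to
#' the reference's within-mask range (rule-2 interpolation), and ranks are
#' preserved.
#'
#' @param moving,reference [volume_grid()]s on a common grid.
#' @param brain_mask Logical array; matching is fit and applied inside it.
#' @param n_quantiles Number of quantile landmarks (>= 2), default 256.
#' @return A [volume_grid()] with matched intensities.
#' @export
histogram_match <- function(moving, reference, brain_mask, n_quantiles = 256L) {
  stopifnot(n_quantiles >= 2L)
  brain_mask <- brain_mask != 0
  mv <- moving$values[brain_mask]
  rv <- reference$values[brain_mask]
  if (length(mv) == 0L || length(rv) == 0L)
    stop("histogram_match: empty brain mask")
  if (max(mv) == min(mv)) {
    warning("histogram_match: constant moving image; identity transform")
    return(moving)
  }
  probs <- seq(0, 1, length.out = n_quantiles)
  qm <- stats::quantile(mv, probs, names = FALSE, type = 7)
  qr <- stats::quantile(rv, probs, names = FALSE, type = 7)
  # collapse duplicated landmarks so approx() sees a strictly monotone map
  keep <- !duplicated(qm)
  qm2 <- qm[keep]
  qr2 <- vapply(split(qr, cumsum(keep)), mean, numeric(1L))
  out <- moving$values
  if (length(qm2) < 2L) {
    out[brain_mask] <- mean(qr)
  } else {
    out[brain_mask] <- stats::approx(qm2, qr2, xout = mv, rule = 2)$y
  }
  volume_grid(out, spacing = moving$spacing)
}

#' Histogram-match every subject of a cohort to a reference subject
#'
#' Each subject's channel `c` is matched against the reference subject's
#' channel `c`; the reference subject itself is returned unchanged.
#'
#' @param subjects List of [subject_record()]s.
#' @param anatomy Shared [anatomy_context()] providing the brain mask.
#' @param reference_subject_id Id of the reference subject; default the
#'   first subject.
#' @param n_quantiles Landmark count, see [histogram_match()].
#' @return List of [subject_record()]s with matched channels.
#' @export
match_cohort <- function(subjects, anatomy,
                         reference_subject_id = subjects[[1L]]$subject_id,
                         n_quantiles = 256L) {
  ids <- vapply(subjects, function(s) s$subject_id, character(1L))
  ref_i <- match(reference_subject_id, ids)
  if (is.na(ref_i)) stop("reference subject not in cohort: ", reference_subject_id)
  ref <- subjects[[ref_i]]
  lapply(subjects, function(s) {
    if (s$subject_id == reference_subject_id) return(s)
    ch <- lapply(channel_names(), function(cn) {
      if (is.null(s$study$channels[[cn]]) || is.null(ref$study$channels[[cn]]))
        stop("registration error: missing channel ", cn)
      histogram_match(s$study$channels[[cn]], ref$study$channels[[cn]],
                      anatomy$brain_mask, n_quantiles)
    })
    names(ch) <- channel_names()
    subject_record(s$subject_id, mpmri_study(s$subject_id, ch), s$mask,
                   subtype = s$subtype)
  })
}
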
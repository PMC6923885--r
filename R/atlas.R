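# Spatial distribution atlases and the 16 location features.
#
# For each subtype an atlas pair (P+, P-) is built by superimposing the
# tumor-core (TC = ET + NET) masks of the subjects with that subtype (P+)
# and of all remaining subjects (P-): P(v) is the fraction of contributing
# subjects whose TC covers voxel v. A new tumor is scored by the mean and
# max of each atlas over its own TC voxels (inclusive of zero-frequency
# voxels), giving per subtype
#   L1 = mean+ - mean-,  L2 = max+ - max-,
#   L3 = (mean+ + eps) / (mean- + eps),  L4 = (max+ + eps) / (max- + eps)
# with eps = 1e-6 guarding the bare ratios against division by zero.

ATLAS_EPS <- 1e-6

#' Build the atlas pair for one subtype
#'
#' @param tc_masks Named list of logical TC arrays, one per training subject,
#'   all on the common grid.
#' @param subtypes Named character vector of subtype labels aligned with
#'   `tc_masks`.
#' @param subtype The target subtype.
#' @return An `atlas_pair`: `subtype`, `P_plus`, `P_minus` (frequency
#'   arrays in `[0, 1]`), `n_plus`, `n_minus`.
#' @export
build_atlas_pair <- function(tc_masks, subtypes, subtype) {
  stopifnot(length(tc_masks) == length(subtypes))
  pos <- which(subtypes == subtype)
  neg <- which(subtypes != subtype)
  if (length(pos) == 0L || length(neg) == 0L)
    stop("atlas error: both groups must be nonempty for subtype ", subtype)
  d <- dim(tc_masks[[1L]])
  acc <- function(ix) {
    s <- array(0, dim = d)
    for (i in ix) {
      m <- tc_masks[[i]]
      if (!identical(dim(m), d)) stop("atlas error: TC masks not on one grid")
      s <- s + (m != 0)
    }
    s / length(ix)
  }
  structure(list(subtype = subtype, P_plus = acc(pos), P_minus = acc(neg),
                 n_plus = length(pos), n_minus = length(neg)),
            class = "atlas_pair")
}

#' Build all four subtype atlas pairs
#'
#' @inheritParams build_atlas_pair
#' @return Named list of `atlas_pair`s in canonical subtype order.
#' @export
build_all_atlases <- function(tc_masks, subtypes) {
  out <- lapply(subtype_levels(), function(st) build_atlas_pair(tc_masks, subtypes, st))
  names(out) <- subtype_levels()
  out
}

#' Location features of one tumor against one atlas pair
#'
#' @param tc_mask Logical TC array of the scored subject (nonempty).
#' @param pair An `atlas_pair` on the same grid.
#' @return Named numeric `L1`, `L2`, `L3`, `L4`.
#' @export
location_features_one <- function(tc_mask, pair) {
  tc_mask <- tc_mask != 0
  if (!any(tc_mask)) stop("empty tumor core: no location features")
  p <- pair$P_plus[tc_mask]
  m <- pair$P_minus[tc_mask]
  mp <- mean(p); mm <- mean(m)
  xp <- max(p); xm <- max(m)
  c(L1 = mp - mm, L2 = xp - xm,
    L3 = (mp + ATLAS_EPS) / (mm + ATLAS_EPS),
    L4 = (xp + ATLAS_EPS) / (xm + ATLAS_EPS))
}

#' All 16 location features of one tumor
#'
#' @param tc_mask Logical TC array (nonempty).
#' @param pairs Named list with one `atlas_pair` per subtype (any order;
#'   assembly is keyed by subtype).
#' @return Named numeric length 16 in canonical subtype x L1..L4 order,
#'   named `loc_<subtype>_L<k>`.
#' @export
all_location_features <- function(tc_mask, pairs) {
  miss <- setdiff(subtype_levels(), names(pairs))
  if (length(miss))
    stop("missing atlas pair(s): ", paste(miss, collapse = ", "))
  out <- numeric(0)
  for (st in subtype_levels()) {
    lf <- location_features_one(tc_mask, pairs[[st]])
    names(lf) <- paste("loc", st, names(lf), sep = "_")
    out <- c(out, lf)
  }
  out
}

#' Write an atlas pair as NIfTI frequency maps
#'
#' @param pair An `atlas_pair`.
#' @param dir Output directory.
#' @param spacing Voxel spacing in mm.
#' @return Invisibly, the two file paths.
#' @export
write_atlas_pair <- function(pair, dir, spacing = c(1, 1, 1)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, sprintf("atlas_%s_plus.nii.gz", pair$subtype))
  p2 <- file.path(dir, sprintf("atlas_%s_minus.nii.gz", pair$subtype))
  write_nifti(volume_grid(pair$P_plus, spacing), p1)
  write_nifti(volume_grid(pair$P_minus, spacing), p2)
  invisible(c(p1, p2))
}
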
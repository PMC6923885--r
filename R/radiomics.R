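# Sub-region radiomic features: volumetrics, surface areas, first-order
# moments, 5-bin histogram percentages, 13-direction GLCM texture, 2D
# morphology on the largest-TC axial slice, ventricle distances and lobe
# proportions.
#
# Conventions (all deliberate, see the methods vignette): moments are
# population moments and kurtosis is non-excess; surface area counts
# exposed voxel faces; perimeter counts exposed pixel edges; GLCM uses a
# single pooled symmetric matrix over the 13 radius-1 offsets with 32
# min-max gray levels inside the region.

#' GLCM specification
#'
#' @param n_gray_levels Number of quantization levels (>= 2).
#' @return List with the radius-1 13-direction displacement set and level count.
#' @export
glcm_spec <- function(n_gray_levels = 32L) {
  stopifnot(n_gray_levels >= 2L)
  list(radius = 1L, directions = glcm_directions(),
       n_gray_levels = as.integer(n_gray_levels))
}

#' The 13 unique radius-1 3D displacement directions
#'
#' The 26-neighborhood modulo sign: each of the 13 returned integer
#' offsets `(dx, dy, dz)` is the lexicographically positive member of an
#' antiparallel pair.
#'
#' @return 13 x 3 integer matrix.
#' @export
glcm_directions <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  keep <- g[, 1] > 0 | (g[, 1] == 0 & g[, 2] > 0) |
    (g[, 1] == 0 & g[, 2] == 0 & g[, 3] > 0)
  out <- g[keep, , drop = FALSE]
  storage.mode(out) <- "integer"
  rownames(out) <- NULL
  out
}

#' Region volumes and brain-volume ratios
#'
#' Volumes in mm^3 of ED, ET, NET and the derived unions TC, WT, plus each
#' volume's ratio over the brain volume. The union identities
#' `vol(TC) = vol(ET) + vol(NET)` and `vol(WT) = vol(TC) + vol(ED)` hold
#' exactly because the three primary labels are disjoint.
#'
#' @param mask A [segmentation_mask()].
#' @param brain_mask Logical array on the same grid.
#' @param spacing Voxel spacing in mm (defaults to the mask's).
#' @return Named numeric vector `volume_*` and `ratio_*`.
#' @export
region_volumes <- function(mask, brain_mask, spacing = mask$spacing) {
  vvol <- prod(spacing)
  nb <- sum(brain_mask != 0)
  if (nb == 0L) stop("empty brain mask")
  regs <- c("ED", "ET", "NET", "TC", "WT")
  vols <- vapply(regs, function(r) sum(region_mask(mask, r)) * vvol, numeric(1L))
  names(vols) <- paste0("volume_", regs)
  ratios <- vols / (nb * vvol)
  names(ratios) <- paste0("ratio_", regs)
  c(vols, ratios)
}

# pad-shift helper: logical array shifted by integer offset, FALSE-filled
shift_mask <- function(m, off) {
  d <- dim(m)
  out <- array(FALSE, dim = d)
  src <- dst <- vector("list", 3L)
  for (a in 1:3) {
    o <- off[a]
    if (o >= 0) { src[[a]] <- seq_len(d[a] - o); dst[[a]] <- seq_len(d[a] - o) + o }
    else { src[[a]] <- seq_len(d[a] + o) - o; dst[[a]] <- seq_len(d[a] + o) }
    if (d[a] - abs(o) <= 0) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
  out
}

#' Surface area of a voxel region
#'
#' Sum of the areas of exposed voxel faces: faces adjoining a non-region
#' voxel or the grid boundary. Exact for the rasterized region (no
#' meshing/smoothing), hence hand-checkable.
#'
#' @param region Logical 3D array.
#' @param spacing Voxel spacing in mm.
#' @return Area in mm^2 (0 for an empty region, with attribute `flag = "empty"`).
#' @export
surface_area <- function(region, spacing = c(1, 1, 1)) {
  region <- region != 0
  if (!any(region)) return(structure(0, flag = "empty"))
  total <- 0
  for (a in 1:3) {
    face <- prod(spacing[-a])
    for (sgn in c(1L, -1L)) {
      off <- c(0L, 0L, 0L); off[a] <- sgn
      nb <- shift_mask(region, off)   # neighbor along -sgn occupied?
      exposed <- region & !shift_mask(region, -off)
      total <- total + sum(exposed) * face
    }
  }
  total
}

#' First-order intensity moments in a region
#'
#' Population moments of the within-region sample. Kurtosis is non-excess
#' (Gaussian -> 3). A constant region has variance 0 and, by convention,
#' skewness and kurtosis 0 (flagged).
#'
#' @param image A [volume_grid()] or numeric array.
#' @param region Logical array.
#' @return Named vector `mean`, `variance`, `skewness`, `kurtosis`.
#' @export
first_order_stats <- function(image, region) {
  v <- if (inherits(image, "volume_grid")) image$values else image
  x <- v[region != 0]
  if (length(x) == 0L)
    return(structure(c(mean = NA_real_, variance = NA_real_,
                       skewness = NA_real_, kurtosis = NA_real_),
                     flag = "empty"))
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0)
    return(structure(c(mean = m, variance = 0, skewness = 0, kurtosis = 0),
                     flag = "constant"))
  c(mean = m, variance = m2,
    skewness = mean((x - m)^3) / m2^1.5,
    kurtosis = mean((x - m)^4) / m2^2)
}

#' Five-bin histogram percentages
#'
#' Percentage of region voxels falling in each of the 5 bins delimited by
#' 6 strictly increasing edges; values outside the edge range are clamped
#' into the end bins, so the percentages always sum to 100.
#'
#' @param image A [volume_grid()] or numeric array.
#' @param region Logical array (nonempty).
#' @param bin_edges Strictly increasing numeric length 6.
#' @return Named numeric length 5, `bin1`..`bin5`.
#' @export
histogram_bins <- function(image, region, bin_edges) {
  v <- if (inherits(image, "volume_grid")) image$values else image
  if (length(bin_edges) != 6L || any(diff(bin_edges) <= 0))
    stop("configuration error: bin_edges must be 6 strictly increasing values")
  x <- v[region != 0]
  if (length(x) == 0L)
    return(structure(stats::setNames(rep(NA_real_, 5L), paste0("bin", 1:5)),
                     flag = "empty"))
  idx <- findInterval(x, bin_edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins = 5L)
  stats::setNames(100 * counts / length(x), paste0("bin", 1:5))
}

# min-max quantization of in-region intensities to 1..G (constant -> all 1)
quantize_region <- function(vals, G) {
  rng <- range(vals)
  if (rng[1] == rng[2]) return(rep(1L, length(vals)))
  q <- floor((vals - rng[1]) / (rng[2] - rng[1]) * G) + 1L
  pmin.int(q, G)
}

#' GLCM texture features (contrast, correlation, energy, homogeneity)
#'
#' Intensities are min-max quantized to `n_gray_levels` inside the region;
#' co-occurrences are counted for voxel pairs both inside the region at
#' each of the 13 radius-1 offsets, symmetrized, pooled into a single
#' matrix and normalized. Standard Haralick formulas follow; a constant
#' region returns contrast 0 and energy/homogeneity/correlation 1 by
#' convention.
#'
#' @param image A [volume_grid()] or numeric array.
#' @param region Logical array.
#' @param spec A [glcm_spec()].
#' @return Named vector `contrast`, `correlation`, `energy`, `homogeneity`.
#' @export
glcm_features <- function(image, region, spec = glcm_spec()) {
  v <- if (inherits(image, "volume_grid")) image$values else image
  region <- region != 0
  n <- sum(region)
  empty <- structure(c(contrast = NA_real_, correlation = NA_real_,
                       energy = NA_real_, homogeneity = NA_real_),
                     flag = "too_small")
  if (n < 2L) return(empty)
  G <- spec$n_gray_levels
  # crop to the region bounding box (+1 margin); co-occurrence pairs are
  # entirely inside the region, so this is exact
  idx <- which(region, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2L, min) - 1L, 1L)
  hi <- pmin(apply(idx, 2L, max) + 1L, dim(v))
  v <- v[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  region <- region[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  qv <- array(0L, dim = dim(v))
  qv[region] <- quantize_region(v[region], G)

  counts <- numeric(G * G)
  dirs <- spec$directions
  for (k in seq_len(nrow(dirs))) {
    off <- dirs[k, ]
    nb_reg <- shift_mask(region, -off)       # voxel+off inside region?
    sel <- region & nb_reg
    if (!any(sel)) next
    d <- dim(v)
    src <- dst <- vector("list", 3L)
    ok <- TRUE
    for (a in 1:3) {
      o <- off[a]
      if (d[a] - abs(o) <= 0) { ok <- FALSE; break }
      if (o >= 0) { src[[a]] <- seq_len(d[a] - o); dst[[a]] <- seq_len(d[a] - o) + o }
      else { src[[a]] <- seq_len(d[a] + o) - o; dst[[a]] <- seq_len(d[a] + o) }
    }
    if (!ok) next
    qs <- array(0L, dim = d)                 # q shifted so qs[x] = q[x + off]
    qs[src[[1]], src[[2]], src[[3]]] <- qv[dst[[1]], dst[[2]], dst[[3]]]
    i <- qv[sel]; j <- qs[sel]
    idx <- (i - 1L) * G + j
    tab <- tabulate(idx, nbins = G * G)
    counts <- counts + tab
    idx2 <- (j - 1L) * G + i                 # symmetrize
    counts <- counts + tabulate(idx2, nbins = G * G)
  }
  tot <- sum(counts)
  if (tot == 0) return(empty)
  P <- matrix(counts / tot, nrow = G, ncol = G, byrow = TRUE)
  lev <- seq_len(G)
  I <- matrix(lev, G, G); J <- t(I)
  contrast <- sum(P * (I - J)^2)
  energy <- sum(P^2)
  homogeneity <- sum(P / (1 + abs(I - J)))
  pi_m <- rowSums(P)
  mu <- sum(lev * pi_m)
  s2 <- sum((lev - mu)^2 * pi_m)
  correlation <- if (s2 == 0) 1 else sum((I - mu) * (J - mu) * P) / s2
  c(contrast = contrast, correlation = correlation,
    energy = energy, homogeneity = homogeneity)
}

#' Select the axial slice with the largest tumor-core area
#'
#' Traverses the volume along z and returns the slice maximizing the TC
#' pixel count (ties broken by the smallest z), with the 2D region masks
#' on that slice.
#'
#' @param mask A [segmentation_mask()].
#' @return List: `z` (1-based slice index), `tc_pixels`, and `regions`
#'   (named list of 2D logical masks for ED/ET/NET/TC).
#' @export
select_morphology_slice <- function(mask) {
  tc <- region_mask(mask, "TC")
  per_z <- apply(tc, 3L, sum)
  if (all(per_z == 0L)) stop("empty tumor core: no morphology slice")
  z <- which.max(per_z)                      # which.max takes the first max
  lab2 <- mask$labels[, , z]
  list(z = z, tc_pixels = per_z[z],
       regions = list(ED = lab2 == LBL_ED, ET = lab2 == LBL_ET,
                      NET = lab2 == LBL_NET,
                      TC = lab2 == LBL_NET | lab2 == LBL_ET))
}

# shoelace polygon area
polygon_area <- function(x, y) {
  n <- length(x)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

#' 2D morphology of a region on one slice
#'
#' Area (pixel count x pixel area), perimeter (exposed pixel-edge length),
#' extent (area over axis-aligned bounding box), solidity (area over the
#' convex hull of the pixel squares), and moment-matched ellipse axis
#' lengths. Second-order central moments treat each pixel as a filled
#' square (discrete variance + h^2/12 per axis), so a w x h rectangle has
#' an axis ratio of exactly w/h. `ecc_ratio` = major/minor >= 1.
#'
#' @param region2d Logical matrix.
#' @param pixel_spacing Length-2 pixel size in mm.
#' @return Named vector: `area`, `perimeter`, `extent`, `solidity`,
#'   `major_axis`, `minor_axis`, `ecc_ratio`.
#' @export
morphology_2d <- function(region2d, pixel_spacing = c(1, 1)) {
  region2d <- region2d != 0
  hx <- pixel_spacing[1]; hy <- pixel_spacing[2]
  idx <- which(region2d, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0L)
    return(structure(stats::setNames(rep(NA_real_, 7L),
      c("area", "perimeter", "extent", "solidity", "major_axis", "minor_axis",
        "ecc_ratio")), flag = "empty"))
  area <- n * hx * hy
  # exposed edges
  d <- dim(region2d)
  pad <- function(m, di, dj) {
    out <- matrix(FALSE, d[1], d[2])
    si <- seq_len(d[1] - abs(di)); sj <- seq_len(d[2] - abs(dj))
    if (length(si) && length(sj))
      out[si + max(di, 0), sj + max(dj, 0)] <- m[si - min(di, 0), sj - min(dj, 0)]
    out
  }
  per <- sum(region2d & !pad(region2d, 1, 0)) * hy +
         sum(region2d & !pad(region2d, -1, 0)) * hy +
         sum(region2d & !pad(region2d, 0, 1)) * hx +
         sum(region2d & !pad(region2d, 0, -1)) * hx
  bbox <- (diff(range(idx[, 1])) + 1) * hx * (diff(range(idx[, 2])) + 1) * hy
  extent <- area / bbox
  # convex hull of pixel corner points
  cx <- c(idx[, 1] - 1, idx[, 1], idx[, 1] - 1, idx[, 1]) * hx
  cy <- c(idx[, 2] - 1, idx[, 2] - 1, idx[, 2], idx[, 2]) * hy
  h <- grDevices::chull(cx, cy)
  hull_area <- polygon_area(cx[h], cy[h])
  solidity <- if (hull_area > 0) area / hull_area else 1
  if (n == 1L) {
    px <- (hx + hy) / 2
    return(structure(c(area = area, perimeter = per, extent = extent,
                       solidity = 1, major_axis = px, minor_axis = px,
                       ecc_ratio = 1), flag = "degenerate"))
  }
  x <- idx[, 1] * hx; y <- idx[, 2] * hy
  cxx <- mean((x - mean(x))^2) + hx^2 / 12
  cyy <- mean((y - mean(y))^2) + hy^2 / 12
  cxy <- mean((x - mean(x)) * (y - mean(y)))
  ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2L), symmetric = TRUE)$values
  ev <- pmax(ev, 0)
  major <- 4 * sqrt(ev[1]); minor <- 4 * sqrt(ev[2])
  ratio <- if (minor > 0) major / minor else Inf
  c(area = area, perimeter = per, extent = extent, solidity = solidity,
    major_axis = major, minor_axis = minor, ecc_ratio = ratio)
}

#' Minimum distance from a region to the ventricles
#'
#' Minimum Euclidean distance (mm) between any region voxel center and any
#' ventricle voxel center; 0 when the masks overlap. The minimum over full
#' voxel sets is attained on the 6-neighborhood boundaries, which are used
#' to keep the pairwise search small.
#'
#' @param region Logical array.
#' @param ventricle_mask Logical array on the same grid (nonempty).
#' @param spacing Voxel spacing in mm.
#' @return Distance in mm (NA with flag for an empty region).
#' @export
ventricle_distance <- function(region, ventricle_mask, spacing = c(1, 1, 1)) {
  region <- region != 0; ventricle_mask <- ventricle_mask != 0
  if (!any(ventricle_mask)) stop("empty ventricle mask")
  if (!any(region)) return(structure(NA_real_, flag = "empty"))
  if (any(region & ventricle_mask)) return(0)
  boundary <- function(m) {
    b <- m & !(shift_mask(m, c(1L, 0L, 0L)) & shift_mask(m, c(-1L, 0L, 0L)) &
               shift_mask(m, c(0L, 1L, 0L)) & shift_mask(m, c(0L, -1L, 0L)) &
               shift_mask(m, c(0L, 0L, 1L)) & shift_mask(m, c(0L, 0L, -1L)))
    which(b, arr.ind = TRUE)
  }
  a <- boundary(region); b <- boundary(ventricle_mask)
  am <- sweep(a, 2L, spacing, `*`); bm <- sweep(b, 2L, spacing, `*`)
  best <- Inf
  step <- max(1L, floor(2e6 / nrow(bm)))
  for (start in seq(1L, nrow(am), by = step)) {
    rows <- start:min(start + step - 1L, nrow(am))
    d2 <- outer(am[rows, 1], bm[, 1], `-`)^2 +
          outer(am[rows, 2], bm[, 2], `-`)^2 +
          outer(am[rows, 3], bm[, 3], `-`)^2
    best <- min(best, min(d2))
  }
  sqrt(best)
}

#' Proportion of TC in each of the 9 brain regions
#'
#' @param tc_mask Logical array (nonempty).
#' @param parcellation Integer array with codes 0 (outside brain) and 1..9.
#' @return Named numeric length 9 (order of [lobe_names()]) summing to 1.
#' @export
lobe_proportions <- function(tc_mask, parcellation) {
  tc_mask <- tc_mask != 0
  if (!any(tc_mask)) stop("empty tumor core")
  codes <- parcellation[tc_mask]
  outside <- sum(codes == 0L)
  if (outside > 0L) {
    warning("lobe_proportions: ", outside,
            " TC voxel(s) outside the brain; renormalizing over in-brain voxels")
    codes <- codes[codes != 0L]
  }
  if (length(codes) == 0L) stop("tumor core entirely outside the brain")
  stats::setNames(tabulate(codes, nbins = 9L) / length(codes), lobe_names())
}

#' Per-subject quantile-derived histogram bin edges
#'
#' Equal-width 5-bin edges between the 1st and 99th percentile of the
#' within-region intensities (type-7 quantiles); degenerate ranges are
#' widened symmetrically by 0.5 so the edges stay strictly increasing.
#'
#' @param vals Numeric vector of within-region intensities.
#' @return Numeric length 6.
#' @export
quantile_bin_edges <- function(vals) {
  q <- stats::quantile(vals, c(0.01, 0.99), names = FALSE, type = 7)
  if (q[2] <= q[1]) q <- q + c(-0.5, 0.5)
  seq(q[1], q[2], length.out = 6L)
}

#' Extract the full radiomic feature vector for one subject
#'
#' Deterministic, documented feature schema (`<family>_<region>_<channel>_<stat>`;
#' families without a channel omit that part): region volumes and
#' brain-volume ratios, surface areas, per (region x channel) first-order
#' moments, 5-bin histogram percentages and GLCM texture, 2D morphology of
#' ED/ET/NET/TC on the largest-TC axial slice, ventricle distances of ED
#' and TC, and the 9 lobe proportions of TC. The 16 atlas location
#' features are appended separately (see [all_location_features()]), since
#' they depend on training-cohort atlases.
#'
#' @param subject A [subject_record()].
#' @param anatomy An [anatomy_context()] on the same grid.
#' @param bin_edges Optional fixed histogram edges (length 6); default is
#'   the per-subject, per-(region, channel) quantile rule of
#'   [quantile_bin_edges()].
#' @param spec A [glcm_spec()].
#' @return Named numeric vector following the schema (possibly with NA for
#'   flagged empty-region intensity features; geometric features of empty
#'   regions are 0).
#' @export
extract_features <- function(subject, anatomy, bin_edges = NULL,
                             spec = glcm_spec()) {
  mask <- subject$mask
  spacing <- mask$spacing
  out <- numeric(0)
  add <- function(x, names) {
    v <- as.numeric(x)
    names(v) <- names
    out <<- c(out, v)
  }
  vols <- region_volumes(mask, anatomy$brain_mask, spacing)
  add(vols, names(vols))
  regs5 <- c("ED", "ET", "NET", "TC", "WT")
  sa <- vapply(regs5, function(r) as.numeric(surface_area(region_mask(mask, r), spacing)),
               numeric(1L))
  add(sa, paste0("surfarea_", regs5))
  regs3 <- c("ED", "ET", "NET")
  for (reg in regs3) {
    rm_ <- region_mask(mask, reg)
    for (ch in channel_names()) {
      img <- subject$study$channels[[ch]]$values
      fo <- first_order_stats(img, rm_)
      add(fo, paste("firstorder", reg, ch, names(fo), sep = "_"))
      edges <- if (is.null(bin_edges)) quantile_bin_edges(img[rm_]) else bin_edges
      hb <- histogram_bins(img, rm_, edges)
      add(hb, paste("hist", reg, ch, names(hb), sep = "_"))
      gl <- glcm_features(img, rm_, spec)
      add(gl, paste("glcm", reg, ch, names(gl), sep = "_"))
    }
  }
  sl <- select_morphology_slice(mask)
  for (reg in c("ED", "ET", "NET", "TC")) {
    mo <- morphology_2d(sl$regions[[reg]], spacing[1:2])
    if (!is.null(attr(mo, "flag")) && identical(attr(mo, "flag"), "empty"))
      mo[c("area", "perimeter")] <- 0       # geometric features of empty regions are 0
    add(mo, paste("morph2d", reg, names(mo), sep = "_"))
  }
  vd_ed <- ventricle_distance(region_mask(mask, "ED"), anatomy$ventricle_mask, spacing)
  vd_tc <- ventricle_distance(region_mask(mask, "TC"), anatomy$ventricle_mask, spacing)
  add(c(vd_ed, vd_tc), c("ventdist_ED", "ventdist_TC"))
  lp <- lobe_proportions(region_mask(mask, "TC"), anatomy$lobe_parcellation)
  add(lp, paste0("lobeprop_", names(lp)))
  out
}

#' Extract the feature table for a cohort
#'
#' Runs [extract_features()] on every subject (manifest order preserved)
#' and optionally appends the 16 location features computed against a
#' given set of subtype atlas pairs.
#'
#' @param subjects List of [subject_record()]s.
#' @param anatomy Shared [anatomy_context()].
#' @param atlases Optional result of [build_all_atlases()]; when supplied
#'   the `loc_*` columns are appended.
#' @param spec A [glcm_spec()].
#' @return Feature table data frame (`subject_id`, features, `subtype`).
#' @export
extract_cohort_features <- function(subjects, anatomy, atlases = NULL,
                                    spec = glcm_spec()) {
  rows <- lapply(subjects, function(s) {
    f <- extract_features(s, anatomy, spec = spec)
    if (!is.null(atlases)) {
      lf <- all_location_features(region_mask(s$mask, "TC"), atlases)
      f <- c(f, lf)
    }
    f
  })
  nm <- names(rows[[1L]])
  for (r in rows) if (!identical(names(r), nm))
    stop("inconsistent feature schema across subjects")
  df <- as.data.frame(do.call(rbind, rows))
  df <- cbind(subject_id = vapply(subjects, function(s) s$subject_id, character(1L)),
              df, stringsAsFactors = FALSE)
  df$subtype <- vapply(subjects, function(s) s$subtype, character(1L))
  rownames(df) <- NULL
  df
}
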
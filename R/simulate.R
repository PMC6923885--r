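# Synthetic glioblastoma cohort generator.
#
# Each subject is three nested ellipsoidal tumor regions (NET core, ET
# shell, ED outer shell) placed inside a shared ellipsoidal brain, with
# Gaussian within-region channel intensities. Subtype identity enters
# through (a) intensity multipliers on specific (region, channel) pairs,
# (b) shell-thickness scaling (volume / surface-area effects), (c) in-plane
# axis-ratio targets (eccentricity effects), and (d) lobe placement priors.
# The default effect directions realize the published qualitative subtype
# signature: proneural has lower and more uniform ET T1-Gd signal,
# neural higher ED FLAIR signal and rounder NET, mesenchymal lower ED
# FLAIR/T2 signal, bigger ED/ET/WT, elongated NET and round ET, classical
# smaller ED/WT surface area.

#' Default simulation configuration
#'
#' Returns the full generative configuration of the synthetic cohort:
#' grid geometry, intensity model, per-subtype effect multipliers and
#' placement priors. All lengths are mm; intensities are arbitrary MR
#' units. `effect_scale = 0` switches every subtype effect off (null
#' cohort); `1` is the default strong-effect world.
#'
#' @param shape Grid shape (voxels per axis).
#' @param spacing Voxel spacing in mm.
#' @param effect_scale Global multiplier in `[0, 1]` interpolating every
#'   effect between "none" and its default strength.
#' @return A `sim_config` list.
#' @export
default_sim_config <- function(shape = c(48L, 48L, 48L),
                               spacing = c(2.5, 2.5, 2.5),
                               effect_scale = 1) {
  sc <- effect_scale
  lerp <- function(x) 1 + sc * (x - 1)   # multiplier -> null at sc = 0
  cfg <- list(
    shape = as.integer(shape),
    spacing = as.numeric(spacing),
    # intensity means per region x channel (rows NET, ET, ED, brain)
    means = matrix(c(
      #  T1   T1GD   T2  FLAIR
        90,   100, 140,  130,   # NET
       100,   200, 120,  120,   # ET
        95,   105, 160,  170,   # ED
       120,   120, 100,   90),  # healthy brain
      nrow = 4L, byrow = TRUE,
      dimnames = list(c("NET", "ET", "ED", "brain"), channel_names())),
    region_sd = 8,       # within-region Gaussian sd
    noise_sd = 4,        # global additive Gaussian noise sd (brain-wide)
    # geometry priors (mm)
    net_axes_mean = c(9, 9, 9), net_axes_sd = 1.2,
    et_shell_mean = 6, et_shell_sd = 0.8,
    ed_shell_mean = 9, ed_shell_sd = 1.2,
    center_jitter_sd = 4,
    max_retry = 10L,
    effects = list(
      # (region, channel) intensity multipliers per subtype
      intensity = list(
        proneural   = list(ET_T1GD = lerp(0.70)),
        neural      = list(ED_FLAIR = lerp(1.30)),
        mesenchymal = list(ED_FLAIR = lerp(0.75), ED_T2 = lerp(0.80)),
        classical   = list()
      ),
      # within-region sd multipliers (uniformity effects)
      sd = list(
        proneural   = list(ET_T1GD = lerp(0.45)),
        neural      = list(), mesenchymal = list(), classical = list()
      ),
      # shell-thickness multipliers: et scales the ET shell, ed the ED shell
      shell = list(
        classical   = list(ed = lerp(0.55)),
        mesenchymal = list(et = lerp(1.55), ed = lerp(1.45)),
        proneural   = list(), neural = list()
      ),
      # in-plane (x/y) axis-ratio targets per region; base is the
      # ratio used for subtypes with no stated eccentricity effect
      ecc_base = list(NET = lerp(1.35), ET = lerp(1.25)),
      ecc = list(
        mesenchymal = list(NET = lerp(1.90), ET = lerp(1.00)),
        neural      = list(NET = lerp(1.00)),
        proneural   = list(), classical = list()
      ),
      # placement prior: mean center offset from brain center (mm);
      # jittered per subject. Distinct lobes give the location atlases
      # a recoverable spatial pattern.
      placement = list(
        classical   = sc * c(0, 28, 8),     # frontal
        mesenchymal = sc * c(-26, -6, -10), # temporal (lateral-inferior)
        proneural   = sc * c(10, -8, 22),   # parietal (superior)
        neural      = sc * c(0, -30, 2)     # occipital (posterior)
      )
    )
  )
  class(cfg) <- c("sim_config", "list")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(length(cfg$shape) == 3L, all(cfg$shape >= 8L),
            all(cfg$spacing > 0),
            cfg$region_sd >= 0, cfg$noise_sd >= 0,
            all(cfg$net_axes_mean > 0), cfg$net_axes_sd >= 0,
            cfg$et_shell_mean > 0, cfg$ed_shell_mean > 0)
  mults <- unlist(cfg$effects[c("intensity", "sd", "shell", "ecc", "ecc_base")])
  if (any(!is.finite(mults)) || any(mults <= 0))
    stop("sim config: effect multipliers must be finite and positive")
  invisible(cfg)
}

# mm coordinates of voxel centers relative to the grid center, per axis
grid_coords_mm <- function(shape, spacing) {
  lapply(1:3, function(a) (seq_len(shape[a]) - (shape[a] + 1) / 2) * spacing[a])
}

# squared normalized ellipsoid distance field: <=1 inside
ellipsoid_field <- function(shape, spacing, center_mm, semi_axes) {
  cs <- grid_coords_mm(shape, spacing)
  dx2 <- ((cs[[1]] - center_mm[1]) / semi_axes[1])^2
  dy2 <- ((cs[[2]] - center_mm[2]) / semi_axes[2])^2
  dz2 <- ((cs[[3]] - center_mm[3]) / semi_axes[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`)
}

#' Build the shared anatomy context of a synthetic cohort
#'
#' Deterministic (no RNG): an ellipsoidal brain filling ~84% of the field
#' of view, two periventricular ellipsoids as ventricles, and a 9-region
#' geometric parcellation (first-match priority rules on mm coordinates)
#' standing in for a lobe atlas.
#'
#' @param config A `sim_config`.
#' @return An [anatomy_context()].
#' @export
synthetic_anatomy <- function(config) {
  shape <- config$shape; spacing <- config$spacing
  fov <- shape * spacing
  brain_ax <- 0.42 * fov
  brain <- ellipsoid_field(shape, spacing, c(0, 0, 0), brain_ax) <= 1
  vent <- (ellipsoid_field(shape, spacing, c(-9, 2, 4), c(6, 14, 7)) <= 1) |
          (ellipsoid_field(shape, spacing, c(9, 2, 4), c(6, 14, 7)) <= 1)
  vent <- vent & brain

  cs <- grid_coords_mm(shape, spacing)
  X <- array(rep(cs[[1]], times = shape[2] * shape[3]), dim = shape)
  Y <- array(rep(rep(cs[[2]], each = shape[1]), times = shape[3]), dim = shape)
  Z <- array(rep(cs[[3]], each = shape[1] * shape[2]), dim = shape)

  lobes <- array(0L, dim = shape)
  assign_lobe <- function(code, cond) {
    sel <- brain & cond & lobes == 0L
    lobes[sel] <<- code
  }
  bz <- brain_ax[3]; by <- brain_ax[2]
  assign_lobe(5L, ellipsoid_field(shape, spacing, c(0, 0, 0), c(20, 20, 16)) <= 1) # basal ganglia
  assign_lobe(6L, abs(X) < 6 & abs(Y) < 26 & Z > 0 & Z < 18)                       # cc/fornix
  assign_lobe(7L, abs(Z) < 10 & abs(Y) < 16 & abs(X) > 20 & abs(X) < 34)           # insula
  assign_lobe(9L, Z < -0.55 * bz & abs(X) < 14 & abs(Y) < 18)                      # brain stem
  assign_lobe(8L, Z < -0.45 * bz & Y < -8)                                         # cerebellum
  assign_lobe(2L, Y > 0.28 * by)                                                   # frontal
  assign_lobe(4L, Y < -0.28 * by)                                                  # occipital
  assign_lobe(1L, Z < 0)                                                           # temporal
  assign_lobe(3L, TRUE)                                                            # parietal
  anatomy_context(brain, vent, lobes, spacing = spacing)
}

#' Generate one synthetic subject
#'
#' Samples nested NET/ET/ED ellipsoid geometry and subtype-modulated
#' channel intensities, fully reproducibly from `(config, subtype, seed)`.
#'
#' @param config A `sim_config` from [default_sim_config()].
#' @param subtype One of [subtype_levels()].
#' @param seed Integer seed; the subject is a pure function of
#'   `(config, subtype, seed)`.
#' @param anatomy Optional precomputed [synthetic_anatomy()] (it is
#'   deterministic, so sharing it across subjects only saves time).
#' @param subject_id Identifier; default derived from subtype and seed.
#' @return A [subject_record()].
#' @export
generate_subject <- function(config, subtype, seed,
                             anatomy = synthetic_anatomy(config),
                             subject_id = sprintf("%s_%d", subtype, seed)) {
  if (!subtype %in% subtype_levels()) stop("unknown subtype: ", subtype)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))

  eff <- config$effects
  shape <- config$shape; spacing <- config$spacing
  brain <- anatomy$brain_mask
  brain_ax <- 0.42 * shape * spacing

  ecc_of <- function(region) {
    r <- eff$ecc[[subtype]][[region]]
    if (is.null(r)) r <- eff$ecc_base[[region]]
    if (is.null(r)) r <- 1
    r
  }
  shell_of <- function(which) {
    m <- eff$shell[[subtype]][[which]]
    if (is.null(m)) 1 else m
  }

  geom <- NULL
  for (try in seq_len(config$max_retry)) {
    net <- pmax(2, stats::rnorm(3, config$net_axes_mean, config$net_axes_sd))
    r <- ecc_of("NET")                       # in-plane ratio via volume-preserving stretch
    net[1] <- net[1] * sqrt(r); net[2] <- net[2] / sqrt(r)
    sh_et <- max(1.5, stats::rnorm(1, config$et_shell_mean, config$et_shell_sd)) * shell_of("et")
    et <- net + sh_et
    r <- ecc_of("ET")
    base_r <- et[1] / et[2]
    adj <- sqrt(r / base_r)
    et[1] <- et[1] * adj; et[2] <- et[2] / adj
    et <- pmax(et, net + 0.8)                # keep strict nesting
    sh_ed <- max(1.5, stats::rnorm(1, config$ed_shell_mean, config$ed_shell_sd)) * shell_of("ed")
    ed <- et + sh_ed
    if (all(ed > et) && all(et > net)) { geom <- list(net = net, et = et, ed = ed); break }
  }
  if (is.null(geom)) stop("synthetic geometry: unsatisfiable nesting after retries")

  place <- eff$placement[[subtype]]
  if (is.null(place)) place <- c(0, 0, 0)
  center <- place + stats::rnorm(3, 0, config$center_jitter_sd)
  lim <- pmax(brain_ax - geom$ed - 2, 0)   # keep the ED envelope inside the brain
  center <- pmin(pmax(center, -lim), lim)

  f_net <- ellipsoid_field(shape, spacing, center, geom$net) <= 1
  f_et  <- ellipsoid_field(shape, spacing, center, geom$et) <= 1
  f_ed  <- ellipsoid_field(shape, spacing, center, geom$ed) <= 1
  labels <- array(0L, dim = shape)
  labels[f_ed & brain] <- LBL_ED
  labels[f_et & brain] <- LBL_ET
  labels[f_net & brain] <- LBL_NET
  if (!any(labels == LBL_NET) || !any(labels == LBL_ET) || !any(labels == LBL_ED))
    stop("synthetic geometry: a tumor region vanished after clipping to brain")
  mask <- segmentation_mask(labels, spacing = spacing)

  imult <- function(region, channel) {
    m <- eff$intensity[[subtype]][[paste(region, channel, sep = "_")]]
    if (is.null(m)) 1 else m
  }
  smult <- function(region, channel) {
    m <- eff$sd[[subtype]][[paste(region, channel, sep = "_")]]
    if (is.null(m)) 1 else m
  }
  chans <- list()
  nbrain <- sum(brain)
  for (ch in channel_names()) {
    v <- array(0, dim = shape)
    v[brain] <- config$means["brain", ch] +
      (if (config$region_sd > 0) stats::rnorm(nbrain, 0, config$region_sd) else 0)
    for (reg in c("ED", "ET", "NET")) {
      sel <- labels == switch(reg, ED = LBL_ED, ET = LBL_ET, NET = LBL_NET)
      nsel <- sum(sel)
      sdr <- config$region_sd * smult(reg, ch)
      v[sel] <- config$means[reg, ch] * imult(reg, ch) +
        (if (sdr > 0) stats::rnorm(nsel, 0, sdr) else 0)
    }
    if (config$noise_sd > 0)
      v[brain] <- v[brain] + stats::rnorm(nbrain, 0, config$noise_sd)
    chans[[ch]] <- volume_grid(v, spacing = spacing)
  }
  subject_record(subject_id, mpmri_study(subject_id, chans), mask, subtype = subtype)
}

# deterministic 31-bit per-subject seed from (master seed, index)
derive_seed <- function(master, index) {
  x <- (as.double(master) %% 2147483647) + 1
  y <- (as.double(index) %% 2147483647) + 1
  as.integer((x * 48271 + y * 16807 + x * y) %% 2147483629) + 1L
}

#' Generate a balanced labeled synthetic cohort
#'
#' @param config A `sim_config`.
#' @param n_per_class Subjects per subtype (>= 1).
#' @param seed Master seed; per-subject seeds are derived deterministically
#'   from `(seed, subject index)` so cohort content is insertion-order
#'   independent and a pure function of `(config, n_per_class, seed)`.
#' @return List with `subjects` (list of [subject_record()]s), `anatomy`
#'   (shared [anatomy_context()]), `manifest` (data frame: subject_id,
#'   subtype, seed), and `seed`.
#' @export
generate_cohort <- function(config, n_per_class, seed) {
  stopifnot(n_per_class >= 1)
  anatomy <- synthetic_anatomy(config)
  subjects <- list()
  man <- list()
  idx <- 0L
  for (st in subtype_levels()) {
    for (i in seq_len(n_per_class)) {
      idx <- idx + 1L
      sid <- sprintf("%s_%03d", st, i)
      s_seed <- derive_seed(seed, idx)
      subjects[[idx]] <- generate_subject(config, st, s_seed, anatomy = anatomy,
                                          subject_id = sid)
      man[[idx]] <- data.frame(subject_id = sid, subtype = st, seed = s_seed,
                               stringsAsFactors = FALSE)
    }
  }
  list(subjects = subjects, anatomy = anatomy,
       manifest = do.call(rbind, man), seed = seed)
}

#' Write a generated cohort to disk
#'
#' Emits the NIfTI + manifest layout that [read_manifest()] /
#' [read_subject()] consume, plus the anatomy volumes and a JSON sidecar
#' echoing the generative configuration and seed.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param config The `sim_config` used (echoed into the sidecar).
#' @return Path of the manifest CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (s in cohort$subjects) {
    sid <- s$subject_id
    paths <- c(t1 = sprintf("%s_t1.nii.gz", sid), t1gd = sprintf("%s_t1gd.nii.gz", sid),
               t2 = sprintf("%s_t2.nii.gz", sid), flair = sprintf("%s_flair.nii.gz", sid),
               mask = sprintf("%s_mask.nii.gz", sid))
    write_nifti(s$study$channels$T1, file.path(dir, paths["t1"]))
    write_nifti(s$study$channels$T1GD, file.path(dir, paths["t1gd"]))
    write_nifti(s$study$channels$T2, file.path(dir, paths["t2"]))
    write_nifti(s$study$channels$FLAIR, file.path(dir, paths["flair"]))
    write_nifti(s$mask$labels, file.path(dir, paths["mask"]), spacing = s$mask$spacing)
    rows[[sid]] <- data.frame(subject_id = sid, t1 = paths["t1"], t1gd = paths["t1gd"],
                              t2 = paths["t2"], flair = paths["flair"],
                              mask = paths["mask"], subtype = s$subtype,
                              stringsAsFactors = FALSE)
  }
  an <- cohort$anatomy
  write_nifti(an$brain_mask + 0L, file.path(dir, "anatomy_brain.nii.gz"), spacing = an$spacing)
  write_nifti(an$ventricle_mask + 0L, file.path(dir, "anatomy_ventricles.nii.gz"), spacing = an$spacing)
  write_nifti(an$lobe_parcellation, file.path(dir, "anatomy_lobes.nii.gz"), spacing = an$spacing)
  man_path <- file.path(dir, "manifest.csv")
  data.table::fwrite(do.call(rbind, rows), man_path)
  if (!is.null(config)) {
    side <- list(schema_version = 1L, seed = cohort$seed,
                 n_per_class = nrow(cohort$manifest) / 4L,
                 config = unclass(config))
    jsonlite::write_json(side, file.path(dir, "simulation.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(man_path)
}

#' Audit realized subtype effects in a cohort
#'
#' Recomputes, for every injected effect channel (intensity means, region
#' volumes, surface areas, 2D eccentricities), the per-subtype group means
#' alongside the direction the generator intended, as ground-truth
#' bookkeeping for recovery tests. Output order is independent of subject
#' order.
#'
#' @param cohort Result of [generate_cohort()].
#' @param config The `sim_config` that generated the cohort (provides the
#'   intended directions; defaults to the package default).
#' @return Data frame: quantity, one group-mean column per subtype
#'   (canonical order), affected subtype and intended direction
#'   (`"higher"`, `"lower"`, or `"null"` when no effect was injected).
#' @export
effect_audit <- function(cohort, config = default_sim_config()) {
  subs <- cohort$subjects
  st <- vapply(subs, function(s) s$subtype, character(1L))
  mean_in <- function(s, reg, ch)
    mean(s$study$channels[[ch]]$values[region_mask(s$mask, reg)])
  vol_of <- function(s, reg) sum(region_mask(s$mask, reg)) * prod(s$mask$spacing)
  sa_of <- function(s, reg) surface_area(region_mask(s$mask, reg), s$mask$spacing)
  ecc_of <- function(s, reg) {
    sl <- select_morphology_slice(s$mask)
    m2 <- sl$regions[[reg]]
    if (!any(m2)) return(NA_real_)
    morphology_2d(m2, s$mask$spacing[1:2])[["ecc_ratio"]]
  }
  quantities <- list(
    ET_T1GD_mean = function(s) mean_in(s, "ET", "T1GD"),
    ED_FLAIR_mean = function(s) mean_in(s, "ED", "FLAIR"),
    ED_T2_mean   = function(s) mean_in(s, "ED", "T2"),
    ED_volume    = function(s) vol_of(s, "ED"),
    ET_volume    = function(s) vol_of(s, "ET"),
    WT_volume    = function(s) vol_of(s, "WT"),
    ED_surface_area = function(s) sa_of(s, "ED"),
    WT_surface_area = function(s) sa_of(s, "WT"),
    NET_eccentricity = function(s) ecc_of(s, "NET"),
    ET_eccentricity  = function(s) ecc_of(s, "ET")
  )
  intended <- list(  # quantity -> c(subtype, direction); resolved vs config below
    ET_T1GD_mean = c("proneural", "ET_T1GD", "intensity"),
    ED_FLAIR_mean = c("mesenchymal", "ED_FLAIR", "intensity"),
    ED_T2_mean = c("mesenchymal", "ED_T2", "intensity"),
    ED_volume = c("mesenchymal", "ed", "shell"),
    ET_volume = c("mesenchymal", "et", "shell"),
    WT_volume = c("mesenchymal", "ed", "shell"),
    ED_surface_area = c("classical", "ed", "shell"),
    WT_surface_area = c("classical", "ed", "shell"),
    NET_eccentricity = c("mesenchymal", "NET", "ecc"),
    ET_eccentricity = c("mesenchymal", "ET", "ecc")
  )
  eff <- config$effects
  rows <- lapply(sort(names(quantities)), function(q) {
    vals <- vapply(subs, quantities[[q]], numeric(1L))
    gm <- vapply(subtype_levels(), function(g) mean(vals[st == g], na.rm = TRUE),
                 numeric(1L))
    tgt <- intended[[q]]
    mult <- eff[[tgt[3]]][[tgt[1]]][[tgt[2]]]
    ref <- if (tgt[3] == "ecc") {
      b <- eff$ecc_base[[tgt[2]]]; if (is.null(b)) 1 else b
    } else 1
    dir <- if (is.null(mult) || isTRUE(all.equal(mult, ref))) "null"
           else if (mult > ref) "higher" else "lower"
    out <- data.frame(quantity = q, subtype = tgt[1], direction = dir,
                      stringsAsFactors = FALSE)
    for (g in subtype_levels()) out[[paste0("mean_", g)]] <- gm[[g]]
    out
  })
  do.call(rbind, rows)
}
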
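# Shared fixtures, built once per test run and memoised. Cohorts are
# generated in code (no stored data); the strong cohort is the default
# stated world, the null cohort has every subtype effect switched off.

.fixtures <- new.env(parent = emptyenv())

# full pipeline on the default strong-effect world: generate -> audit ->
# extract (with TC masks kept for per-fold atlases). Histogram matching is
# deliberately NOT applied: the simulator emits all subjects on one
# intensity scale already, and quantile-matching near-identical
# whole-brain distributions only perturbs the tumor tail (see vignette).
strong_cohort_data <- function() {
  if (is.null(.fixtures$strong)) {
    cfg <- default_sim_config()
    coh <- generate_cohort(cfg, 30, seed = 1)
    audit <- effect_audit(coh, cfg)
    subjects <- coh$subjects
    anatomy <- coh$anatomy
    rm(coh)
    tc <- cohort_tc_masks(subjects)
    atlases <- build_all_atlases(tc$tc_masks, tc$subtypes)
    tab <- extract_cohort_features(subjects, anatomy, atlases = atlases)
    keep_subjects <- subjects[c(1L, 31L, 61L, 91L)]  # one per subtype
    rm(subjects); gc(verbose = FALSE)
    .fixtures$strong <- list(cfg = cfg, tab = tab, tc = tc, audit = audit,
                             anatomy = anatomy, subjects = keep_subjects,
                             atlases = atlases)
  }
  .fixtures$strong
}

# zero-effect world: identical machinery, every subtype effect off
null_cohort_data <- function() {
  if (is.null(.fixtures$null)) {
    cfg <- default_sim_config(effect_scale = 0)
    coh <- generate_cohort(cfg, 30, seed = 2)
    audit <- effect_audit(coh, cfg)
    subjects <- coh$subjects
    anatomy <- coh$anatomy
    rm(coh)
    tc <- cohort_tc_masks(subjects)
    atlases <- build_all_atlases(tc$tc_masks, tc$subtypes)
    tab <- extract_cohort_features(subjects, anatomy, atlases = atlases)
    rm(subjects); gc(verbose = FALSE)
    .fixtures$null <- list(cfg = cfg, tab = tab, tc = tc, audit = audit,
                           anatomy = anatomy)
  }
  .fixtures$null
}

# tiny labeled table with a known planted structure, for model unit tests
toy_model_table <- function(n_per_class = 20L, p_noise = 27L, effect = 3,
                            seed = 42L) {
  withr::local_seed(seed)
  lab <- rep(subtype_levels(), each = n_per_class)
  n <- length(lab)
  X <- matrix(stats::rnorm(n * (3L + p_noise)), n, 3L + p_noise)
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  X[, 1] <- X[, 1] + effect * (lab == "classical")
  X[, 2] <- X[, 2] + effect * (lab == "mesenchymal")
  X[, 3] <- X[, 3] + effect * (lab == "proneural")
  list(X = X, labels = lab)
}

# brute-force GLCM oracle: enumerate every voxel pair at every offset
glcm_oracle <- function(vol, region, G = 8L) {
  region <- region != 0
  vals <- vol[region]
  rng <- range(vals)
  q <- array(0L, dim = dim(vol))
  q[region] <- if (rng[1] == rng[2]) 1L else
    pmin.int(floor((vol[region] - rng[1]) / (rng[2] - rng[1]) * G) + 1L, G)
  dirs <- glcm_directions()
  counts <- matrix(0, G, G)
  d <- dim(vol)
  for (k in seq_len(nrow(dirs))) {
    off <- dirs[k, ]
    for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
      if (!region[x, y, z]) next
      x2 <- x + off[1]; y2 <- y + off[2]; z2 <- z + off[3]
      if (x2 < 1 || x2 > d[1] || y2 < 1 || y2 > d[2] || z2 < 1 || z2 > d[3]) next
      if (!region[x2, y2, z2]) next
      i <- q[x, y, z]; j <- q[x2, y2, z2]
      counts[i, j] <- counts[i, j] + 1
      counts[j, i] <- counts[j, i] + 1
    }
  }
  P <- counts / sum(counts)
  lev <- seq_len(G)
  I <- matrix(lev, G, G); J <- t(I)
  mu <- sum(lev * rowSums(P))
  s2 <- sum((lev - mu)^2 * rowSums(P))
  c(contrast = sum(P * (I - J)^2),
    correlation = if (s2 == 0) 1 else sum((I - mu) * (J - mu) * P) / s2,
    energy = sum(P^2),
    homogeneity = sum(P / (1 + abs(I - J))))
}

# pairwise Mann-Whitney AUC oracle with half credit for ties
auc_oracle <- function(scores, positive) {
  pos <- scores[positive != 0]; neg <- scores[positive == 0]
  total <- 0
  for (a in pos) for (b in neg)
    total <- total + (a > b) + 0.5 * (a == b)
  total / (length(pos) * length(neg))
}

# tiny deterministic volume helper
box_mask <- function(shape, from, to) {
  m <- array(FALSE, dim = shape)
  m[from[1]:to[1], from[2]:to[2], from[3]:to[3]] <- TRUE
  m
}
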
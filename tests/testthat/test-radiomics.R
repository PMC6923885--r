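# radiomics: volumetrics, surface area, moments, histograms, GLCM,
# morphology, distances, lobe proportions, full-vector assembly.

test_that("region volumes, unions and ratios follow the counting rules", {
  lab <- array(0L, c(6, 6, 6))
  lab[1:2, 1:5, 1] <- 4L   # 10 ET
  lab[4, 1:5, 1] <- 1L     # 5 NET
  m <- segmentation_mask(lab, spacing = c(1, 1, 1))
  brain <- array(TRUE, c(6, 6, 6))
  v <- region_volumes(m, brain)
  expect_identical(unname(v["volume_TC"]), 15)
  expect_identical(unname(v["volume_WT"]), unname(v["volume_TC"]))  # empty ED
  expect_identical(unname(v["volume_ED"]), 0)
  expect_identical(unname(v["ratio_TC"]), 15 / 216)
  # anisotropic spacing: product rule
  m2 <- segmentation_mask(lab, spacing = c(1, 1, 2))
  v2 <- region_volumes(m2, brain)
  expect_identical(unname(v2["volume_ET"]), 20)
  expect_error(region_volumes(m, array(FALSE, c(6, 6, 6))), "brain")
})

test_that("surface area counts exposed faces exactly", {
  one <- box_mask(c(5, 5, 5), c(3, 3, 3), c(3, 3, 3))
  expect_identical(as.numeric(surface_area(one, c(1, 1, 1))), 6)
  bar <- box_mask(c(5, 5, 5), c(2, 3, 3), c(3, 3, 3))
  expect_identical(as.numeric(surface_area(bar, c(1, 1, 1))), 10)
  # spacing (1,1,2): a 1x1x2 mm box has 2 faces of 1x1 and 4 of 1x2 -> 10
  expect_identical(as.numeric(surface_area(one, c(1, 1, 2))), 10)
  # faces at the grid boundary count as exposed
  corner <- box_mask(c(2, 2, 2), c(1, 1, 1), c(1, 1, 1))
  expect_identical(as.numeric(surface_area(corner, c(1, 1, 1))), 6)
  empty <- array(FALSE, c(3, 3, 3))
  expect_identical(as.numeric(surface_area(empty)), 0)
  expect_identical(attr(surface_area(empty), "flag"), "empty")
})

test_that("first-order moments are population moments with the stated conventions", {
  vol <- array(0, c(3, 1, 1)); vol[] <- c(1, 2, 3)
  reg <- array(TRUE, c(3, 1, 1))
  fo <- first_order_stats(vol, reg)
  expect_identical(unname(fo["mean"]), 2)
  expect_identical(unname(fo["variance"]), 2 / 3)
  vol[] <- c(-4, 0, 4)
  expect_identical(unname(first_order_stats(vol, reg)["skewness"]), 0)
  vol[] <- 7
  fo <- first_order_stats(vol, reg)
  expect_identical(unname(fo[c("variance", "skewness", "kurtosis")]), c(0, 0, 0))
  expect_identical(attr(fo, "flag"), "constant")
  withr::local_seed(2)
  x <- rnorm(200)
  vol2 <- array(x, c(200, 1, 1)); reg2 <- array(TRUE, c(200, 1, 1))
  fo2 <- first_order_stats(vol2, reg2)
  m <- mean(x)
  expect_equal(unname(fo2["kurtosis"]), mean((x - m)^4) / mean((x - m)^2)^2)
})

test_that("histogram percentages count, clamp and sum to 100", {
  reg <- array(TRUE, c(7, 1, 1))
  vol <- array(c(0.1, 0.2, 0.3, 1.1, 1.2, 1.3, 1.4), c(7, 1, 1))
  hb <- histogram_bins(vol, reg, bin_edges = c(0, 1, 2, 3, 4, 5))
  expect_equal(unname(hb), c(300 / 7, 400 / 7, 0, 0, 0))
  expect_equal(sum(hb), 100)
  # all mass in one bin
  vol[] <- 0.5
  expect_equal(unname(histogram_bins(vol, reg, c(0, 1, 2, 3, 4, 5))),
               c(100, 0, 0, 0, 0))
  # out-of-range values clamp into the end bins
  vol[] <- c(-10, 0.5, 99, 99, 0.5, 0.5, -10)
  hb <- histogram_bins(vol, reg, c(0, 1, 2, 3, 4, 5))
  expect_equal(unname(hb), c(500 / 7, 0, 0, 0, 200 / 7))
  expect_error(histogram_bins(vol, reg, c(0, 1, 1, 3, 4, 5)), "configuration")
  # uniform fill across 5 equal bins
  vol10 <- array(rep(c(0.5, 1.5, 2.5, 3.5, 4.5), 2), c(10, 1, 1))
  expect_equal(unname(histogram_bins(vol10, array(TRUE, c(10, 1, 1)),
                                     c(0, 1, 2, 3, 4, 5))), rep(20, 5))
})

test_that("there are exactly 13 pairwise non-antiparallel GLCM directions", {
  d <- glcm_directions()
  expect_identical(nrow(d), 13L)
  expect_true(all(abs(d) <= 1L))
  for (i in 1:12) for (j in (i + 1):13)
    expect_false(all(d[i, ] == -d[j, ]) || all(d[i, ] == d[j, ]))
})

test_that("GLCM features match the exhaustive pair-enumeration oracle", {
  withr::local_seed(10)
  for (r in 1:6) {
    vol <- array(rnorm(6^3), c(6, 6, 6))
    reg <- array(FALSE, c(6, 6, 6)); reg[2:5, 2:5, 2:5] <- TRUE
    got <- glcm_features(vol, reg, glcm_spec(n_gray_levels = 8L))
    want <- glcm_oracle(vol, reg, G = 8L)
    expect_equal(unname(got), unname(want), tolerance = 1e-12)
  }
})

test_that("GLCM conventions and bounds hold", {
  reg <- array(FALSE, c(4, 4, 4)); reg[2:3, 2:3, 2:3] <- TRUE
  vol <- array(5, c(4, 4, 4))
  g <- glcm_features(vol, reg)
  expect_equal(unname(g), c(0, 1, 1, 1))
  withr::local_seed(13)
  vol <- array(rnorm(64), c(4, 4, 4))
  g <- glcm_features(vol, reg, glcm_spec(4L))
  expect_gt(g[["energy"]], 0); expect_lte(g[["energy"]], 1)
  expect_gt(g[["homogeneity"]], 0); expect_lte(g[["homogeneity"]], 1)
  expect_gte(g[["contrast"]], 0)
  lone <- array(FALSE, c(4, 4, 4)); lone[1, 1, 1] <- TRUE
  expect_identical(attr(glcm_features(vol, lone), "flag"), "too_small")
})

test_that("morphology slice selection maximizes TC area with smallest-z ties", {
  lab <- array(0L, c(4, 4, 5))
  lab[1, 1, 2] <- 4L                         # 1 TC pixel at z=2
  lab[1:3, 1:3, 3] <- 1L                     # 9 at z=3
  lab[1:3, 1:3, 4] <- 4L                     # 9 at z=4 (tie -> z=3)
  lab[1:2, 1, 5] <- 2L                       # ED-only slice must not win
  sl <- select_morphology_slice(segmentation_mask(lab))
  expect_identical(sl$z, 3L)
  expect_identical(sum(sl$regions$TC), 9L)
  # ED never drives selection
  lab2 <- lab; lab2[, , 5] <- 2L
  expect_identical(select_morphology_slice(segmentation_mask(lab2))$z, 3L)
  expect_error(select_morphology_slice(segmentation_mask(array(2L, c(2, 2, 2)))),
               "empty tumor core")
})

test_that("2D morphology matches closed-form values on squares and rectangles", {
  sq <- matrix(FALSE, 14, 14); sq[3:12, 3:12] <- TRUE
  m <- morphology_2d(sq, c(1, 1))
  expect_identical(unname(m["area"]), 100)
  expect_identical(unname(m["perimeter"]), 40)
  expect_identical(unname(m["extent"]), 1)
  expect_equal(unname(m["solidity"]), 1)
  expect_equal(unname(m["ecc_ratio"]), 1)
  rect <- matrix(FALSE, 24, 9); rect[2:21, 2:6] <- TRUE   # 20 x 5
  m2 <- morphology_2d(rect, c(1, 1))
  expect_equal(unname(m2["ecc_ratio"]), 4)                # continuous moments
  expect_equal(unname(m2["major_axis"]) / unname(m2["minor_axis"]), 4)
  one <- matrix(FALSE, 3, 3); one[2, 2] <- TRUE
  m3 <- morphology_2d(one, c(2, 2))
  expect_identical(unname(m3[c("major_axis", "minor_axis", "ecc_ratio")]),
                   c(2, 2, 1))
  expect_identical(attr(m3, "flag"), "degenerate")
})

test_that("ventricle distance is a symmetric point-set distance", {
  shape <- c(8, 8, 8)
  a <- box_mask(shape, c(1, 1, 1), c(1, 1, 1))
  b <- array(FALSE, shape); b[4, 5, 1] <- TRUE   # offset (3, 4, 0)
  expect_identical(ventricle_distance(a, b, c(1, 1, 1)), 5)
  expect_identical(ventricle_distance(b, a, c(1, 1, 1)), 5)
  expect_identical(ventricle_distance(a, a, c(1, 1, 1)), 0)
  # spacing scales physical distance
  expect_identical(ventricle_distance(a, b, c(2, 2, 1)), 10)
  expect_identical(attr(ventricle_distance(array(FALSE, shape), b), "flag"),
                   "empty")
  expect_error(ventricle_distance(a, array(FALSE, shape)), "ventricle")
})

test_that("lobe proportions count TC voxels per region and sum to 1", {
  parc <- array(0L, c(10, 10, 2))
  parc[1:5, , ] <- 2L; parc[6:10, , ] <- 1L
  tc <- array(FALSE, c(10, 10, 2))
  tc[4:5, 1:5, 1] <- TRUE   # 10 voxels in lobe 2 (frontal)
  lp <- lobe_proportions(tc, parc)
  expect_identical(unname(lp["frontal"]), 1)
  expect_identical(sum(lp), 1)
  tc[6:8, 1:7, 1] <- TRUE   # add 21 voxels in lobe 1 -> 10/31 vs 21/31
  lp <- lobe_proportions(tc, parc)
  expect_equal(unname(lp["temporal"]), 21 / 31)
  expect_equal(unname(lp["frontal"]), 10 / 31)
  # voxels outside the brain renormalize with a warning
  parc[6:10, , ] <- 0L
  expect_warning(lp2 <- lobe_proportions(tc, parc), "outside")
  expect_identical(unname(lp2["frontal"]), 1)
})

test_that("feature extraction is deterministic and translation-invariant", {
  cfg <- default_sim_config(shape = c(32L, 32L, 32L), spacing = c(3, 3, 3))
  an <- synthetic_anatomy(cfg)
  s <- generate_subject(cfg, "proneural", seed = 17, anatomy = an)
  f1 <- extract_features(s, an)
  f2 <- extract_features(s, an)
  expect_identical(f1, f2)

  # rigid whole-voxel shift: intensity/texture/morphology unchanged
  shift3 <- function(arr, k) {
    out <- array(if (is.integer(arr)) 0L else 0, dim(arr))
    out[(1 + k):dim(arr)[1], , ] <- arr[1:(dim(arr)[1] - k), , ]
    out
  }
  s2 <- s
  s2$mask$labels <- shift3(s$mask$labels, 2L)
  for (ch in channel_names())
    s2$study$channels[[ch]]$values <- shift3(s$study$channels[[ch]]$values, 2L)
  f3 <- extract_features(s2, an)
  loc_dep <- grepl("^(ventdist|lobeprop)", names(f1))
  expect_equal(f1[!loc_dep], f3[!loc_dep], tolerance = 1e-12)
})

test_that("the assembled vector matches the documented schema exactly", {
  d <- strong_cohort_data()
  f <- extract_features(d$subjects[[1]], d$anatomy)
  # 5 volumes + 5 ratios + 5 surface areas + 12 x (4 + 5 + 4) + 4 x 7
  # morphology + 2 ventricle distances + 9 lobe proportions = 210
  expect_length(f, 210L)
  expect_identical(sum(grepl("^hist_", names(f))), 60L)
  expect_identical(sum(grepl("^glcm_", names(f))), 48L)
  expect_identical(sum(grepl("^firstorder_", names(f))), 48L)
  # with location features appended the total is 226
  expect_identical(length(feature_columns(d$tab)), 226L)
})
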
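# location_atlas: frequency-map construction, L1-L4 scoring, leakage
# sensitivity.

toy_tc <- function(shape, ...) {
  m <- array(FALSE, shape)
  for (ix in list(...)) m[ix[1], ix[2], ix[3]] <- TRUE
  m
}

test_that("atlas frequencies equal hand-counted coverage fractions", {
  shape <- c(3L, 3L, 1L)
  masks <- list(a = toy_tc(shape, c(1, 1, 1), c(2, 1, 1)),
                b = toy_tc(shape, c(1, 1, 1)),
                c = toy_tc(shape, c(3, 3, 1)))
  st <- c(a = "proneural", b = "proneural", c = "neural")
  pair <- build_atlas_pair(masks, st, "proneural")
  expect_identical(pair$n_plus, 2L); expect_identical(pair$n_minus, 1L)
  expect_identical(pair$P_plus[1, 1, 1], 1)      # both proneural cover it
  expect_identical(pair$P_plus[2, 1, 1], 0.5)    # one of two
  expect_identical(pair$P_minus[3, 3, 1], 1)
  expect_identical(pair$P_minus[1, 1, 1], 0)
  expect_true(all(pair$P_plus >= 0 & pair$P_plus <= 1))
  # identical subtype subjects give a 0/1 indicator atlas
  pair2 <- build_atlas_pair(list(masks$a, masks$a, masks$c),
                            c("proneural", "proneural", "neural"), "proneural")
  expect_true(all(pair2$P_plus %in% c(0, 1)))
  expect_identical(pair2$P_plus == 1, masks$a)
  # disjoint TCs give disjoint supports
  expect_false(any(pair$P_plus > 0 & pair$P_minus > 0))
  expect_error(build_atlas_pair(masks, c(a = "neural", b = "neural", c = "neural"),
                                "proneural"), "atlas error")
})

test_that("L1-L4 match hand arithmetic on a printed toy atlas", {
  shape <- c(3L, 3L, 1L)
  tc <- toy_tc(shape, c(1, 1, 1), c(2, 1, 1))
  pair <- structure(list(subtype = "proneural",
                         P_plus = array(0, shape), P_minus = array(0, shape),
                         n_plus = 2L, n_minus = 4L), class = "atlas_pair")
  pair$P_plus[1, 1, 1] <- 0.5; pair$P_plus[2, 1, 1] <- 1.0
  pair$P_minus[1, 1, 1] <- 0.25; pair$P_minus[2, 1, 1] <- 0.25
  lf <- location_features_one(tc, pair)
  eps <- 1e-6
  expect_equal(unname(lf["L1"]), 0.75 - 0.25)
  expect_equal(unname(lf["L2"]), 1.0 - 0.25)
  expect_equal(unname(lf["L3"]), (0.75 + eps) / (0.25 + eps))
  expect_equal(unname(lf["L4"]), (1.0 + eps) / (0.25 + eps))
})

test_that("symmetric atlases give (0, 0, 1, 1); scaling behaves homogeneously", {
  shape <- c(4L, 4L, 2L)
  withr::local_seed(6)
  P <- array(runif(prod(shape)), shape)
  tc <- array(FALSE, shape); tc[2:3, 2:3, 1] <- TRUE
  pair <- structure(list(subtype = "classical", P_plus = P, P_minus = P,
                         n_plus = 1L, n_minus = 1L), class = "atlas_pair")
  lf <- location_features_one(tc, pair)
  expect_equal(unname(lf), c(0, 0, 1, 1))
  # scaling both maps by c scales L1, L2 by c; L3, L4 stable up to eps
  pair2 <- pair; pair2$P_plus <- 0.5 * P; pair2$P_minus <- 0.5 * P + 0.1
  lf2 <- location_features_one(tc, pair2)
  pair3 <- pair2
  pair3$P_plus <- 2 * pair2$P_plus; pair3$P_minus <- 2 * pair2$P_minus
  lf3 <- location_features_one(tc, pair3)
  expect_equal(unname(lf3["L1"]), 2 * unname(lf2["L1"]))
  expect_equal(unname(lf3["L2"]), 2 * unname(lf2["L2"]))
  expect_equal(unname(lf3["L3"]), unname(lf2["L3"]) * 2 *
                 (mean(pair2$P_minus[tc]) + 1e-6) / (2 * mean(pair2$P_minus[tc]) + 1e-6),
               tolerance = 1e-4)
})

test_that("all_location_features yields 16 canonically ordered, key-assembled values", {
  shape <- c(3L, 3L, 1L)
  tc <- toy_tc(shape, c(2, 2, 1))
  withr::local_seed(8)
  pairs <- lapply(subtype_levels(), function(st)
    structure(list(subtype = st, P_plus = array(runif(prod(shape)), shape),
                   P_minus = array(runif(prod(shape)), shape),
                   n_plus = 1L, n_minus = 3L), class = "atlas_pair"))
  names(pairs) <- subtype_levels()
  lf <- all_location_features(tc, pairs)
  expect_length(lf, 16L)
  expect_identical(names(lf)[1:4],
                   paste0("loc_classical_L", 1:4))
  # order of supplied pairs is irrelevant (keyed assembly)
  expect_identical(all_location_features(tc, rev(pairs)), lf)
  expect_error(all_location_features(tc, pairs[1:3]), "missing atlas pair")
  # symmetric pairs -> (0,0,1,1) x 4
  sym <- lapply(pairs, function(p) { p$P_minus <- p$P_plus; p })
  expect_equal(unname(all_location_features(tc, sym)), rep(c(0, 0, 1, 1), 4L))
})

test_that("held-out masks never contribute to the atlases that score them", {
  d <- strong_cohort_data()
  tab <- d$tab
  fold <- radsubtype:::make_folds(tab$subtype, 5L, seed = 3L)
  f <- 1L
  tr_ids <- tab$subject_id[fold != f]
  te_id <- tab$subject_id[fold == f][1L]
  atl <- build_all_atlases(d$tc$tc_masks[tr_ids],
                           d$tc$subtypes[tr_ids])
  # construction sensitivity: adding the held-out subject changes P_plus
  atl_leaky <- build_all_atlases(d$tc$tc_masks[c(tr_ids, te_id)],
                                 d$tc$subtypes[c(tr_ids, te_id)])
  st <- d$tc$subtypes[[te_id]]
  expect_false(identical(atl[[st]]$P_plus, atl_leaky[[st]]$P_plus))
  # the CV path builds atlases from training rows only
  art <- cv_fit_fold(tab, fold, f, tc_masks = d$tc$tc_masks)
  expect_identical(art$atlases[[st]]$P_plus, atl[[st]]$P_plus)
  expect_identical(art$atlases[[st]]$n_plus + art$atlases[[st]]$n_minus,
                   length(tr_ids))
})
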
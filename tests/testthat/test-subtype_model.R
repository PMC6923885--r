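# subtype_model: standardization, SFS, OvR training, distances, fusion,
# metrics, ROC, cross-validation bookkeeping.

test_that("standardization uses population moments and drops constants", {
  X <- cbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(0, 10, 20))
  st <- standardize_fit(X)
  Z <- standardize_apply(st, X)
  expect_equal(unname(Z[, "a"]), c(-1, 0, 1) * sqrt(3 / 2))  # 1.2247...
  expect_false("b" %in% colnames(Z))
  expect_equal(colMeans(Z), c(a = 0, c = 0))
  expect_equal(sqrt(colMeans(Z^2)), c(a = 1, c = 1))
})

test_that("the linear SVM solver finds a max-margin separator", {
  # separable 1D problem: margin midpoint at 0
  X <- matrix(c(-3, -2, -1, 1, 2, 3), ncol = 1)
  y <- c(-1, -1, -1, 1, 1, 1)
  fit <- radsubtype:::.svm_fit_cpp(X, y, 10, rep(1, 6))
  expect_gt(fit$w[1], 0)
  expect_lt(abs(fit$b / fit$w[1]), 0.1)   # decision boundary near 0
  # decision values respect the labels
  expect_true(all(sign(X %*% fit$w + fit$b) == y))
})

test_that("SFS picks the separating feature first and honors its stopping rule", {
  d <- toy_model_table(n_per_class = 15L, p_noise = 12L, effect = 4, seed = 7)
  ybin <- ifelse(d$labels == "classical", 1, -1)
  sel <- sfs_select(d$X, ybin, seed = 2)
  expect_identical(sel$features[1L], 1L)   # f1 carries the classical signal
  # threshold = Inf selects exactly one feature
  cfg <- default_model_config(); cfg$sfs_threshold <- Inf
  sel1 <- sfs_select(d$X, ybin, cfg, seed = 2)
  expect_length(sel1$features, 1L)
  # duplicated columns: the lower-index copy wins the tie
  X2 <- cbind(d$X[, 1, drop = FALSE], d$X)
  colnames(X2) <- paste0("g", seq_len(ncol(X2)))
  sel2 <- sfs_select(X2, ybin, cfg, seed = 2)
  expect_identical(sel2$features[1L], 1L)
  # determinism
  expect_identical(sfs_select(d$X, ybin, seed = 2)$features, sel$features)
})

test_that("train_ovr separates separable data and is seed-deterministic", {
  d <- toy_model_table(n_per_class = 20L, effect = 5, seed = 11)
  b <- train_ovr(d$X, d$labels, seed = 4)
  expect_named(b, subtype_levels())
  pred <- vapply(seq_len(nrow(d$X)), function(i)
    fuse(decision_distances(b, d$X[i, ])), character(1L))
  expect_gte(mean(pred == d$labels), 0.95)
  b2 <- train_ovr(d$X, d$labels, seed = 4)
  expect_identical(lapply(b, `[[`, "feature_names"),
                   lapply(b2, `[[`, "feature_names"))
  expect_error(train_ovr(d$X[d$labels != "neural", ],
                         d$labels[d$labels != "neural"]), "absent")
})

test_that("decision distances are geometric and behave under translation", {
  d <- toy_model_table(n_per_class = 10L, p_noise = 3L, effect = 4, seed = 13)
  b <- train_ovr(d$X, d$labels, seed = 5)
  m <- b$classical
  # a row placed exactly on the hyperplane has distance 0
  row <- d$X[1, ]
  z <- (row[m$feature_names] - m$center) / m$scale
  z_on <- z - (sum(m$w * z) + m$b) / sum(m$w^2) * m$w   # project onto plane
  row_on <- row
  row_on[m$feature_names] <- z_on * m$scale + m$center
  expect_lt(abs(decision_distances(b, row_on)["classical"]), 1e-10)
  # moving along the unit weight vector by delta changes the distance by delta
  delta <- 0.37
  u <- m$w / sqrt(sum(m$w^2))
  row_moved <- row_on
  row_moved[m$feature_names] <- (z_on + delta * u) * m$scale + m$center
  expect_equal(unname(decision_distances(b, row_moved)["classical"]), delta,
               tolerance = 1e-10)
  # joint rescaling of weights and offset leaves the distance unchanged
  b3 <- b
  b3$classical$w <- 7.7 * m$w; b3$classical$b <- 7.7 * m$b
  expect_equal(decision_distances(b3, row), decision_distances(b, row))
  expect_error(decision_distances(b, row[-match(m$feature_names[1], names(row))]),
               "missing feature")
})

test_that("fusion takes the max distance with canonical tie-breaking", {
  expect_identical(fuse(c(proneural = 0.45, neural = 3.54,
                          mesenchymal = -2.43, classical = 5.32)), "classical")
  expect_identical(fuse(c(classical = 1, mesenchymal = 1,
                          proneural = 1, neural = 1)), "classical")
  expect_identical(fuse(c(classical = -5, mesenchymal = -2,
                          proneural = -9, neural = -1)), "neural")
  expect_error(fuse(c(classical = 1, mesenchymal = NaN,
                      proneural = 0, neural = 0)), "non-finite")
  expect_error(fuse(c(a = 1, b = 2, c = 3, d = 4)), "keyed")
})

test_that("metrics reproduce definition arithmetic and hand-counted confusion", {
  lab <- c("classical", "classical", "mesenchymal", "mesenchymal",
           "proneural", "neural", "neural", "neural")
  prd <- c("classical", "mesenchymal", "mesenchymal", "mesenchymal",
           "classical", "neural", "neural", "proneural")
  r <- compute_metrics(prd, lab)
  expect_equal(r$overall$accuracy, 100 * 5 / 8)
  # per-class recalls: 1/2, 2/2, 0/1, 2/3
  expect_equal(r$overall$balanced_accuracy, 100 * mean(c(1/2, 1, 0, 2/3)))
  expect_identical(as.vector(r$overall$confusion["classical", ]),
                   c(1L, 1L, 0L, 0L))
  cm <- r$per_subtype$mesenchymal
  expect_equal(cm$sensitivity, 100)       # both mesenchymal called
  expect_equal(cm$specificity, 100 * 5 / 6)
  expect_equal(cm$balanced_accuracy, (100 + 100 * 5 / 6) / 2)
  # perfect predictions
  p <- compute_metrics(lab, lab, scores = local({
    s <- matrix(0, 8, 4, dimnames = list(NULL, subtype_levels()))
    for (i in seq_along(lab)) s[i, lab[i]] <- 1
    s
  }))
  expect_equal(p$overall$accuracy, 100)
  expect_equal(p$per_subtype$neural$auc, 1)
})

test_that("AUC equals the Mann-Whitney pair-counting oracle, ties at half", {
  withr::local_seed(19)
  for (r in 1:8) {
    n <- sample(6:20, 1)
    pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(pos) || all(pos)) next
    scores <- sample(seq(-2, 2, by = 0.5), n, replace = TRUE)  # forces ties
    expect_equal(as.numeric(auc_rank(scores, pos)), auc_oracle(scores, pos))
    expect_equal(roc_curve(scores, pos)$auc, auc_oracle(scores, pos))
  }
})

test_that("ROC curves are monotone from (0,0) to (1,1) with edge conventions", {
  pos <- c(TRUE, TRUE, FALSE, FALSE)
  r <- roc_curve(c(2, 1.5, 1, 0.5), pos)
  expect_equal(r$auc, 1)
  expect_identical(r$fpr[1], 0); expect_identical(r$tpr[1], 0)
  expect_identical(utils::tail(r$fpr, 1), 1); expect_identical(utils::tail(r$tpr, 1), 1)
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
  expect_equal(roc_curve(rep(1, 4), pos)$auc, 0.5)
  expect_identical(attr(roc_curve(1:3, c(TRUE, TRUE, TRUE)), "flag"),
                   "single_class")
})

test_that("cross-validation covers every subject exactly once, deterministically", {
  d <- toy_model_table(n_per_class = 10L, p_noise = 5L, effect = 4, seed = 23)
  tab <- data.frame(subject_id = sprintf("s%02d", seq_len(nrow(d$X))), d$X,
                    subtype = d$labels, stringsAsFactors = FALSE)
  r <- cross_validate(tab, k = 5, seed = 6)
  expect_identical(sort(r$predictions$subject_id), sort(tab$subject_id))
  expect_identical(anyDuplicated(r$predictions$subject_id), 0L)
  expect_true(all(table(r$folds, tab$subtype) %in% 2L))  # stratified 10/5
  expect_identical(sum(r$overall$confusion), 40L)
  r2 <- cross_validate(tab, k = 5, seed = 6)
  expect_identical(r$predictions$predicted, r2$predictions$predicted)
  expect_gte(r$overall$accuracy, 75)
  expect_error(cross_validate(tab, k = 11, seed = 1), "smaller k")
})
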
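# One-vs-rest max-margin subtype classification.
#
# Four binary linear SVMs (classical/mesenchymal/proneural/neural vs rest),
# each trained with sequential forward feature selection and an inner-CV
# regularization search on the training fold only, evaluated under
# stratified 5-fold cross-validation and fused by maximum geometric
# distance to the hyperplane. Squared-hinge primal solver in src/svm.cpp;
# class-weighted loss counters the ~1:3 one-vs-rest imbalance.

#' Default model configuration
#'
#' @return List: `C_grid` (2^-5..2^5), `sfs_threshold` (balanced-accuracy
#'   improvement needed to keep growing the feature set), `sfs_max`
#'   (feature-count cap), `inner_k` (inner CV folds), `sfs_C` (fixed
#'   regularization used during selection).
#' @export
default_model_config <- function() {
  list(C_grid = 2^(-5:5), sfs_threshold = 0.005, sfs_max = 20L,
       inner_k = 3L, sfs_C = 1)
}

#' Fit column standardization statistics
#'
#' Population mean/sd per column; constant columns (sd 0) are flagged for
#' exclusion so downstream margins stay finite.
#'
#' @param X Numeric matrix (>= 2 rows).
#' @return List: `mean`, `sd`, `keep` (logical).
#' @export
standardize_fit <- function(X) {
  stopifnot(nrow(X) >= 2L)
  mu <- colMeans(X)
  sd_ <- sqrt(colMeans(sweep(X, 2L, mu)^2))
  list(mean = mu, sd = sd_, keep = sd_ > 0)
}

#' Apply standardization statistics
#'
#' @param stats Result of [standardize_fit()].
#' @param X Matrix with the same columns.
#' @return Matrix of the kept columns, centered and scaled.
#' @export
standardize_apply <- function(stats, X) {
  X <- X[, stats$keep, drop = FALSE]
  sweep(sweep(X, 2L, stats$mean[stats$keep]), 2L, stats$sd[stats$keep], `/`)
}

# stratified fold assignment: per class, shuffled then dealt round-robin
make_folds <- function(labels, k, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    ix <- which(labels == cl)
    if (length(ix) < k)
      stop("class ", cl, " has fewer than k = ", k,
           " members; use a smaller k")
    fold[ix[sample.int(length(ix))]] <- rep_len(seq_len(k), length(ix))
  }
  fold
}

#' Sequential forward feature selection
#'
#' Greedy growth of the feature subset: at each step the candidate whose
#' addition maximizes inner-CV balanced accuracy (class-weighted linear
#' SVM, fixed `sfs_C`) is added; growth stops when the best improvement is
#' below `threshold` or `max_features` is reached. At least one feature is
#' always selected; exact score ties go to the lowest column index. The
#' inner folds are fixed once from `seed`, making selection deterministic.
#'
#' @param X Numeric feature matrix (training fold only).
#' @param ybin Numeric vector in `{-1, +1}`.
#' @param config See [default_model_config()].
#' @param seed Seed for the inner fold assignment.
#' @return List: `features` (ordered selected column indices), `names`,
#'   `scores` (inner-CV balanced accuracy after each addition).
#' @export
sfs_select <- function(X, ybin, config = default_model_config(), seed = 1L) {
  stopifnot(all(ybin %in% c(-1, 1)), length(unique(ybin)) == 2L)
  p <- ncol(X)
  fold <- make_folds(ifelse(ybin > 0, "pos", "neg"), config$inner_k, seed)
  selected <- integer(0)
  scores <- numeric(0)
  current <- -Inf
  repeat {
    cand <- setdiff(seq_len(p), selected)
    if (length(cand) == 0L || length(selected) >= config$sfs_max) break
    sc <- .sfs_score_cpp(X, ybin, as.integer(selected), as.integer(cand),
                         as.integer(fold), config$sfs_C)
    best <- which(sc >= max(sc) - 1e-12)[1L]   # lowest index wins ties
    gain <- sc[best] - (if (length(selected)) current else -Inf)
    if (length(selected) > 0L && gain < config$sfs_threshold) break
    selected <- c(selected, cand[best])
    current <- sc[best]
    scores <- c(scores, current)
  }
  list(features = selected, names = colnames(X)[selected], scores = scores)
}

# inner-CV balanced accuracy of a fixed feature set at one C
cv_set_score <- function(X, ybin, set, fold, C) {
  if (length(set) == 1L) {
    .sfs_score_cpp(X, ybin, integer(0), as.integer(set), as.integer(fold), C)
  } else {
    .sfs_score_cpp(X, ybin, as.integer(set[-length(set)]),
                   as.integer(set[length(set)]), as.integer(fold), C)
  }
}

# balanced class weights (positive rows get n / (2 n+), negatives n / (2 n-))
balanced_weights <- function(ybin) {
  n <- length(ybin); npos <- sum(ybin > 0); nneg <- n - npos
  ifelse(ybin > 0, n / (2 * npos), n / (2 * nneg))
}

#' Train one binary max-margin model
#'
#' Standardizes the selected training columns, fits the class-weighted
#' squared-hinge linear SVM at the given C, and records everything needed
#' to score unseen rows.
#'
#' @param X Training feature matrix.
#' @param ybin Labels in `{-1, +1}`.
#' @param features Ordered selected column indices.
#' @param C Regularization parameter.
#' @param target The positive-class subtype name.
#' @return A `binary_model`.
#' @export
fit_binary_model <- function(X, ybin, features, C, target) {
  Xs <- X[, features, drop = FALSE]
  st <- standardize_fit(Xs)
  if (!all(st$keep)) {
    features <- features[st$keep]
    Xs <- X[, features, drop = FALSE]
    st <- standardize_fit(Xs)
  }
  Z <- standardize_apply(st, Xs)
  fit <- .svm_fit_cpp(Z, as.numeric(ybin), C, balanced_weights(ybin))
  structure(list(target = target, features = features,
                 feature_names = colnames(X)[features],
                 center = st$mean, scale = st$sd,
                 w = as.numeric(fit$w), b = as.numeric(fit$b), C = C),
            class = "binary_model")
}

#' Train the four one-vs-rest models on one training fold
#'
#' Per subtype (canonical order): one-vs-rest recoding, sequential forward
#' selection, inner grid search over the regularization parameter on the
#' selected set, and a final class-weighted fit on the full training fold.
#'
#' @param X Training feature matrix (rows = subjects, named columns).
#' @param labels Subtype labels (all four present).
#' @param config See [default_model_config()].
#' @param seed Seed driving the inner fold assignments.
#' @return An `ovr_bundle`: named list of four `binary_model`s.
#' @export
train_ovr <- function(X, labels, config = default_model_config(), seed = 1L) {
  miss <- setdiff(subtype_levels(), unique(labels))
  if (length(miss))
    stop("subtype(s) absent from training fold: ", paste(miss, collapse = ", "))
  models <- lapply(seq_along(subtype_levels()), function(i) {
    st <- subtype_levels()[i]
    ybin <- ifelse(labels == st, 1, -1)
    sel <- sfs_select(X, ybin, config, seed = seed + i)
    fold <- make_folds(ifelse(ybin > 0, "pos", "neg"), config$inner_k, seed + i)
    cs <- vapply(config$C_grid, function(C)
      cv_set_score(X, ybin, sel$features, fold, C), numeric(1L))
    C_best <- config$C_grid[which(cs >= max(cs) - 1e-12)[1L]]  # tie -> smaller C
    fit_binary_model(X, ybin, sel$features, C_best, st)
  })
  names(models) <- subtype_levels()
  structure(models, class = "ovr_bundle")
}

#' Signed geometric distances of one row to the four hyperplanes
#'
#' Per model, the standardized row's signed distance to the decision
#' hyperplane (score divided by the weight norm), positive toward the
#' model's target subtype — so the four scores are commensurable before
#' the argmax fusion.
#'
#' @param bundle An `ovr_bundle`.
#' @param row Named numeric vector (or 1-row matrix) containing every
#'   selected feature.
#' @return Named numeric length 4 in canonical subtype order.
#' @export
decision_distances <- function(bundle, row) {
  if (is.matrix(row)) row <- row[1L, ]
  vapply(subtype_levels(), function(st) {
    m <- bundle[[st]]
    miss <- setdiff(m$feature_names, names(row))
    if (length(miss))
      stop("missing feature(s) for model ", st, ": ", paste(miss, collapse = ", "))
    x <- as.numeric(row[m$feature_names])
    z <- (x - m$center) / m$scale
    (sum(m$w * z) + m$b) / sqrt(sum(m$w^2))
  }, numeric(1L))
}

#' Fuse four one-vs-rest distances into a subtype call
#'
#' Argmax of the four signed distances; exact ties are broken by canonical
#' subtype order.
#'
#' @param distances Named numeric length 4 keyed by the subtypes (any
#'   order; re-keyed canonically).
#' @return One of [subtype_levels()].
#' @export
fuse <- function(distances) {
  if (!all(subtype_levels() %in% names(distances)))
    stop("distances must be keyed by the four subtypes")
  d <- distances[subtype_levels()]
  if (any(!is.finite(d))) stop("non-finite decision distance")
  subtype_levels()[which.max(d)]   # which.max returns the first maximum
}

#' Rank-based AUC (Mann-Whitney, ties counted half)
#'
#' @param scores Numeric scores.
#' @param positive Logical (or 0/1) positive-class indicator.
#' @return AUC in `[0, 1]`; NA with a flag if a class is absent.
#' @export
auc_rank <- function(scores, positive) {
  positive <- positive != 0
  npos <- sum(positive); nneg <- sum(!positive)
  if (npos == 0L || nneg == 0L) return(structure(NA_real_, flag = "single_class"))
  r <- rank(scores)
  (sum(r[positive]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' ROC curve and trapezoidal AUC
#'
#' Points from every distinct score threshold (rule: call positive when
#' `score >= t`), monotone from (0, 0) to (1, 1); the trapezoid AUC equals
#' the rank-based AUC including the half-credit tie convention.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param positive Positive-class indicator.
#' @return List: `fpr`, `tpr` (ordered), `auc`.
#' @export
roc_curve <- function(scores, positive) {
  positive <- positive != 0
  npos <- sum(positive); nneg <- sum(!positive)
  if (npos == 0L || nneg == 0L)
    return(structure(list(fpr = NA, tpr = NA, auc = NA_real_), flag = "single_class"))
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- positive[ord]
  grp <- cumsum(!duplicated(s))            # tied scores collapse to one point
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / npos)
  fpr <- c(0, fp[last] / nneg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

#' Performance metrics from pooled predictions
#'
#' Per subtype one-vs-rest: sensitivity (% positives called positive),
#' specificity (% negatives called negative), accuracy (% correct
#' one-vs-rest calls), balanced accuracy ((sens + spec) / 2) and AUC from
#' the class's decision distances; overall: 4-way accuracy, 4-way balanced
#' accuracy (mean per-class recall) and the confusion matrix. Percentages
#' are on the 0-100 scale.
#'
#' @param predictions Character vector of fused calls.
#' @param labels True subtype labels.
#' @param scores Optional matrix (rows = subjects, columns = subtypes) of
#'   decision distances for AUC/ROC.
#' @return A `performance_report` list.
#' @export
compute_metrics <- function(predictions, labels, scores = NULL) {
  stopifnot(length(predictions) == length(labels))
  lv <- subtype_levels()
  conf <- table(factor(labels, lv), factor(predictions, lv))
  per <- lapply(lv, function(st) {
    pos <- labels == st
    if (!any(pos))
      return(list(accuracy = NA, balanced_accuracy = NA, sensitivity = NA,
                  specificity = NA, auc = NA, flag = "class_absent"))
    ppos <- predictions == st
    sens <- 100 * sum(ppos & pos) / sum(pos)
    spec <- 100 * sum(!ppos & !pos) / sum(!pos)
    out <- list(accuracy = 100 * mean(ppos == pos),
                balanced_accuracy = (sens + spec) / 2,
                sensitivity = sens, specificity = spec, auc = NA_real_)
    if (!is.null(scores)) {
      out$auc <- as.numeric(auc_rank(scores[, st], pos))
      out$roc <- roc_curve(scores[, st], pos)[c("fpr", "tpr")]
    }
    out
  })
  names(per) <- lv
  recalls <- vapply(lv, function(st)
    if (any(labels == st)) 100 * mean(predictions[labels == st] == st) else NA_real_,
    numeric(1L))
  structure(list(
    per_subtype = per,
    overall = list(accuracy = 100 * mean(predictions == labels),
                   balanced_accuracy = mean(recalls, na.rm = TRUE),
                   confusion = conf),
    n = length(labels)), class = "performance_report")
}

#' Fit the training artifacts of one cross-validation fold
#'
#' The single code path used by [cross_validate()] for every fold:
#' rebuilds the location atlases from the training subjects only (when
#' `tc_masks` is given), recomputes the 16 `loc_*` columns for all rows
#' against those training atlases, takes imputation medians from the
#' training rows, and trains the one-vs-rest bundle on the training rows.
#' Exported as the audit hook for leakage tests: every returned artifact
#' must be a pure function of the training rows.
#'
#' @param table Feature table.
#' @param fold Integer fold assignment per row.
#' @param f The held-out fold index.
#' @param tc_masks Optional named list of TC masks (per-fold atlas rebuild).
#' @param config Model configuration.
#' @param seed Cross-validation seed.
#' @return List: `bundle` (trained `ovr_bundle`), `atlases` (or NULL),
#'   `medians` (training-fold imputation medians), `X` (imputed feature
#'   matrix for all rows, loc columns recomputed against training atlases).
#' @export
cv_fit_fold <- function(table, fold, f, tc_masks = NULL,
                        config = default_model_config(), seed = 1L) {
  labels <- table$subtype
  tr <- fold != f
  tab_f <- table
  atl <- NULL
  if (!is.null(tc_masks)) {
    atl <- build_all_atlases(tc_masks[table$subject_id[tr]], labels[tr])
    loc <- t(vapply(table$subject_id,
                    function(id) all_location_features(tc_masks[[id]], atl),
                    numeric(16L)))
    for (cn in colnames(loc)) tab_f[[cn]] <- loc[, cn]
  }
  Xall <- as.matrix(tab_f[, feature_columns(tab_f), drop = FALSE])
  med <- apply(Xall[tr, , drop = FALSE], 2L, stats::median, na.rm = TRUE)
  for (j in seq_len(ncol(Xall))) {
    nas <- is.na(Xall[, j])
    if (any(nas)) Xall[nas, j] <- med[j]
  }
  bundle <- train_ovr(Xall[tr, , drop = FALSE], labels[tr], config,
                      seed = seed * 100L + f)
  list(bundle = bundle, atlases = atl, medians = med, X = Xall)
}

#' Leakage-safe stratified k-fold cross-validation
#'
#' Per fold: location atlases are rebuilt from the training subjects only
#' and the 16 `loc_*` columns recomputed for everyone against those
#' atlases; missing-feature imputation medians come from the training
#' rows; [train_ovr()] runs on the training rows; the held-out rows are
#' scored by [decision_distances()] and fused. All held-out predictions
#' are pooled into one report. No statistic is ever computed on test-fold
#' rows.
#'
#' @param table Feature table (`subject_id`, features, `subtype`).
#' @param k Number of folds (every class needs >= k members).
#' @param seed Seed driving fold assignment and inner selection.
#' @param tc_masks Optional named list of logical TC arrays keyed by
#'   subject id; required for per-fold atlas rebuilding (without it any
#'   existing `loc_*` columns are used as-is, which is only leakage-safe
#'   if they were computed externally per fold).
#' @param config Model configuration.
#' @return A `performance_report` with `$predictions` (data frame:
#'   subject_id, subtype, predicted, fold, one distance column per class),
#'   `$folds`, `$seed`.
#' @export
cross_validate <- function(table, k = 5L, seed = 1L, tc_masks = NULL,
                           config = default_model_config()) {
  stopifnot("subtype" %in% names(table))
  labels <- table$subtype
  fold <- make_folds(labels, k, seed)
  lv <- subtype_levels()
  pred <- character(nrow(table))
  dists <- matrix(NA_real_, nrow(table), 4L, dimnames = list(NULL, lv))
  for (f in seq_len(k)) {
    art <- cv_fit_fold(table, fold, f, tc_masks = tc_masks, config = config,
                       seed = seed)
    te <- which(fold == f)
    for (i in te) {
      d <- decision_distances(art$bundle, art$X[i, ])
      dists[i, ] <- d
      pred[i] <- fuse(d)
    }
  }
  rep_ <- compute_metrics(pred, labels, scores = dists)
  rep_$predictions <- data.frame(subject_id = table$subject_id, subtype = labels,
                                 predicted = pred, fold = fold, dists,
                                 stringsAsFactors = FALSE)
  rep_$folds <- fold
  rep_$seed <- seed
  rep_
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("Performance report (n = %d)\n", x$n))
  for (st in subtype_levels()) {
    p <- x$per_subtype[[st]]
    cat(sprintf("  %-12s acc %5.1f%%  bal %5.1f%%  sens %5.1f%%  spec %5.1f%%  AUC %s\n",
                st, p$accuracy, p$balanced_accuracy, p$sensitivity, p$specificity,
                ifelse(is.na(p$auc), "--", sprintf("%.2f", p$auc))))
  }
  cat(sprintf("  overall      acc %5.1f%%  bal %5.1f%%\n",
              x$overall$accuracy, x$overall$balanced_accuracy))
  invisible(x)
}
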
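# Univariate association screening of features against the four subtypes:
# tie-corrected Kruskal-Wallis rank test with chi-square p-values (an
# exact/Monte-Carlo permutation option exists for oracle checks),
# Benjamini-Hochberg control over the screen, and group-wise normalized
# histograms.

#' Kruskal-Wallis rank test
#'
#' Mid-ranks over the pooled sample;
#' `H = [12 / (N(N+1))] * sum(R_j^2 / n_j) - 3(N+1)` divided by the tie
#' correction `1 - sum(t^3 - t) / (N^3 - N)`; p-value from the chi-square
#' approximation with `groups - 1` degrees of freedom, or from a label
#' permutation when `n_perm > 0`.
#'
#' @param values Numeric vector.
#' @param groups Group labels (coerced to factor), >= 2 nonempty groups.
#' @param n_perm If > 0, additionally compute a Monte-Carlo permutation
#'   p-value from `n_perm` label shuffles (seeded by `perm_seed`).
#' @param perm_seed Seed for the permutation draw.
#' @return List: `H`, `p` (chi-square), `df`, and when requested `p_perm`
#'   and `perm_se` (binomial Monte-Carlo standard error). All-identical
#'   values give `H = 0`, `p = 1`, `flag = "constant"`.
#' @export
kruskal_wallis <- function(values, groups, n_perm = 0L, perm_seed = 1L) {
  g <- factor(groups)
  stopifnot(length(values) == length(g))
  ok <- !is.na(values) & !is.na(g)
  values <- values[ok]; g <- droplevels(g[ok])
  n_j <- table(g)
  if (nlevels(g) < 2L || any(n_j < 1L) || length(values) < 3L)
    stop("kruskal_wallis: need >= 2 nonempty groups and >= 3 observations")
  N <- length(values)
  H_of <- function(vals) {
    r <- rank(vals)                       # mid-ranks for ties
    R <- tapply(r, g, sum)
    H <- 12 / (N * (N + 1)) * sum(R^2 / n_j) - 3 * (N + 1)
    t_ <- table(vals)
    corr <- 1 - sum(t_^3 - t_) / (N^3 - N)
    if (corr <= 0) return(NA_real_)       # all values identical
    H / corr
  }
  if (length(unique(values)) == 1L)
    return(list(H = 0, p = 1, df = nlevels(g) - 1L, flag = "constant"))
  H <- H_of(values)
  df <- nlevels(g) - 1L
  out <- list(H = H, p = stats::pchisq(H, df = df, lower.tail = FALSE), df = df)
  if (n_perm > 0L) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(as.integer(perm_seed))
    hits <- 0L
    for (b in seq_len(n_perm)) {
      if (H_of(sample(values)) >= H - 1e-12) hits <- hits + 1L
    }
    out$p_perm <- (hits + 1L) / (n_perm + 1L)
    out$perm_se <- sqrt(out$p_perm * (1 - out$p_perm) / n_perm)
  }
  out
}

#' Screen every feature of a table against the subtype labels
#'
#' One tie-corrected Kruskal-Wallis test per feature column, sorted by
#' ascending p, with Benjamini-Hochberg q-values and per-group medians.
#' The direction flag names the group whose median is farthest from the
#' overall median.
#'
#' @param table Feature table with a `subtype` column.
#' @return Data frame: `feature`, `H`, `p`, `q`, `median_<subtype>` (4),
#'   `extreme_group`, `extreme_side` (`"low"`/`"high"`), `flag`.
#' @export
screen_features <- function(table) {
  stopifnot("subtype" %in% names(table))
  g <- table$subtype
  feats <- feature_columns(table)
  rows <- lapply(feats, function(f) {
    x <- table[[f]]
    if (length(unique(x[!is.na(x)])) <= 1L) {
      kw <- list(H = 0, p = 1, flag = "constant")
    } else {
      kw <- kruskal_wallis(x, g)
      kw$flag <- NA_character_
    }
    med <- vapply(subtype_levels(), function(s) stats::median(x[g == s], na.rm = TRUE),
                  numeric(1L))
    dev <- med - stats::median(x, na.rm = TRUE)
    ext <- which.max(abs(dev))
    out <- data.frame(feature = f, H = kw$H, p = kw$p, stringsAsFactors = FALSE)
    for (s in subtype_levels()) out[[paste0("median_", s)]] <- med[[s]]
    out$extreme_group <- subtype_levels()[ext]
    out$extreme_side <- if (dev[ext] < 0) "low" else "high"
    out$flag <- kw$flag
    out
  })
  res <- do.call(rbind, rows)
  res$q <- stats::p.adjust(res$p, method = "BH")
  res <- res[order(res$p, res$feature), ]
  rownames(res) <- NULL
  res[, c("feature", "H", "p", "q", paste0("median_", subtype_levels()),
          "extreme_group", "extreme_side", "flag")]
}

#' Per-group normalized histograms on shared bin edges
#'
#' @param values Numeric vector.
#' @param groups Group labels.
#' @param n_bins Number of equal-width bins spanning the pooled range.
#' @return List: `edges` (length `n_bins + 1`) and `freq`, a named list of
#'   per-group frequency vectors each summing to 1 (empty groups are
#'   flagged with all-NA frequencies).
#' @export
group_histograms <- function(values, groups, n_bins = 10L) {
  g <- factor(groups)
  rng <- range(values, finite = TRUE)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  freq <- lapply(levels(g), function(lev) {
    x <- values[g == lev]
    if (length(x) == 0L) return(rep(NA_real_, n_bins))
    idx <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
    tabulate(idx, nbins = n_bins) / length(x)
  })
  names(freq) <- levels(g)
  list(edges = edges, freq = freq)
}
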
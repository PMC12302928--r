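## Differential-feature screening: per-feature univariate tests, FDR
## control, VIP + p selection with up/down calls, and the deterministic
## clustering order used for heatmaps.

#' Per-feature one-way ANOVA
#'
#' Classical one-way F-test of group differences for each feature,
#' computed on log intensities. Features with zero between- and
#' within-group variance (all samples identical) are assigned p = 1 by
#' convention. With two groups the F statistic equals the square of the
#' pooled-variance t statistic.
#'
#' @param x feature table or samples x features matrix (no missing values).
#' @param groups group label per sample (>= 2 groups, each >= 2 samples);
#'   taken from the table's column data when omitted.
#' @param log log-transform feature-table intensities (default TRUE).
#' @return Data frame with `feature_id`, `F`, `p_raw`.
#' @export
anovaPerFeature <- function(x, groups = NULL, log = TRUE) {
  if (is.null(groups)) {
    if (!methods::is(x, "SummarizedExperiment"))
      stop("'groups' is required for a plain matrix")
    groups <- sampleGroups(x)
  }
  m <- .analysisMatrix(x, log = log)
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("at least two groups required")
  if (any(table(g) < 2L)) stop("every group needs at least 2 samples")
  n <- nrow(m)
  k <- nlevels(g)
  grand <- colMeans(m)
  ss_between <- numeric(ncol(m))
  ss_within <- numeric(ncol(m))
  for (lv in levels(g)) {
    rows <- g == lv
    gm <- colMeans(m[rows, , drop = FALSE])
    ss_between <- ss_between + sum(rows) * (gm - grand)^2
    ss_within <- ss_within +
      colSums(sweep(m[rows, , drop = FALSE], 2L, gm)^2)
  }
  # all-identical features: 0/0 F; declared convention p = 1
  degenerate <- ss_within < .Machine$double.eps & ss_between < 1e-12
  Fstat <- (ss_between / (k - 1)) / (ss_within / (n - k))
  Fstat[degenerate] <- 0
  p <- stats::pf(Fstat, k - 1, n - k, lower.tail = FALSE)
  p[degenerate] <- 1
  data.frame(feature_id = colnames(m), F = Fstat, p_raw = p,
             row.names = NULL)
}

#' Per-feature Welch t-test for a two-group comparison
#'
#' Welch's unequal-variance t-test on log intensities for every feature,
#' plus the log2 fold change of the first group over the second computed
#' on the un-logged group means.
#'
#' @param x feature table or samples x features matrix.
#' @param groups group label per sample.
#' @param pair character(2): the two groups compared, first over second.
#' @param log log-transform feature-table intensities (default TRUE).
#' @return Data frame with `feature_id`, `t`, `p_raw`, `log2_fold_change`.
#' @export
welchPerFeature <- function(x, groups = NULL, pair, log = TRUE) {
  if (is.null(groups)) {
    if (!methods::is(x, "SummarizedExperiment"))
      stop("'groups' is required for a plain matrix")
    groups <- sampleGroups(x)
  }
  stopifnot(length(pair) == 2L)
  if (!all(pair %in% groups))
    stop("pair groups not present in the data: ",
         paste(setdiff(pair, groups), collapse = ", "))
  raw <- if (methods::is(x, "SummarizedExperiment")) intensityMatrix(x) else x
  m <- .analysisMatrix(x, log = log)
  i1 <- groups == pair[1]
  i2 <- groups == pair[2]
  m1 <- colMeans(m[i1, , drop = FALSE])
  m2 <- colMeans(m[i2, , drop = FALSE])
  v1 <- apply(m[i1, , drop = FALSE], 2L, stats::var)
  v2 <- apply(m[i2, , drop = FALSE], 2L, stats::var)
  n1 <- sum(i1); n2 <- sum(i2)
  se2 <- v1 / n1 + v2 / n2
  # zero-variance features: p = 1 when the means also agree, else certain
  degenerate <- se2 < .Machine$double.eps
  tstat <- (m1 - m2) / sqrt(pmax(se2, .Machine$double.xmin))
  df <- se2^2 / pmax((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1),
                     .Machine$double.xmin)
  df[degenerate] <- 1
  p <- 2 * stats::pt(-abs(tstat), df)
  same <- degenerate & abs(m1 - m2) < .Machine$double.eps^0.5
  tstat[same] <- 0
  p[same] <- 1
  tstat[degenerate & !same] <- sign(m1 - m2)[degenerate & !same] * Inf
  p[degenerate & !same] <- 0
  mu1 <- colMeans(raw[i1, , drop = FALSE])
  mu2 <- colMeans(raw[i2, , drop = FALSE])
  # fold change is defined on the (positive) intensity scale only
  lfc <- rep(NA_real_, length(mu1))
  ok <- mu1 > 0 & mu2 > 0
  lfc[ok] <- log2(mu1[ok] / mu2[ok])
  data.frame(feature_id = colnames(m), t = tstat, p_raw = p,
             log2_fold_change = lfc, row.names = NULL)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of raw p-values; adjusted
#' values are clipped at 1, monotone in rank and never below the raw
#' p-value, and the input order is preserved.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Adjusted p-values in the input order.
#' @export
bhAdjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Select differential features by VIP and p-value
#'
#' Applies the combined screening rule: a feature is selected iff its VIP
#' score strictly exceeds `vip_threshold` and its (raw or BH-adjusted)
#' p-value is below `p_threshold`. Direction is `up` when the log2 fold
#' change of the first group over the second is positive.
#'
#' @param vip,p,log2fc aligned per-feature vectors (named by feature id,
#'   or supply `feature_id`).
#' @param feature_id optional feature ids.
#' @param vip_threshold strict VIP cutoff, default 1.
#' @param p_threshold strict p cutoff, default 0.05.
#' @param use_adjusted apply [bhAdjust()] to `p` before thresholding
#'   (default FALSE: raw p, the usual companion of a VIP filter).
#' @return Data frame with `feature_id`, `vip`, `p_raw`, `p_adjusted`,
#'   `log2_fold_change`, `selected`, `direction`; the numbers of up- and
#'   down-regulated selections are attached as attribute `counts`.
#' @export
selectDifferential <- function(vip, p, log2fc, feature_id = NULL,
                               vip_threshold = 1, p_threshold = 0.05,
                               use_adjusted = FALSE) {
  n <- length(vip)
  if (length(p) != n || length(log2fc) != n)
    stop("'vip', 'p' and 'log2fc' must have equal length")
  if (is.null(feature_id))
    feature_id <- if (!is.null(names(vip))) names(vip) else
      paste0("feature_", seq_len(n))
  p_adj <- bhAdjust(p)
  p_used <- if (use_adjusted) p_adj else p
  selected <- vip > vip_threshold & p_used < p_threshold
  direction <- ifelse(log2fc > 0, "up", "down")
  res <- data.frame(feature_id = feature_id, vip = vip, p_raw = p,
                    p_adjusted = p_adj, log2_fold_change = log2fc,
                    selected = selected, direction = direction,
                    row.names = NULL)
  attr(res, "counts") <- c(up = sum(selected & direction == "up"),
                           down = sum(selected & direction == "down"))
  res
}

#' Run a pairwise differential screen
#'
#' Convenience wrapper for one two-group comparison: fits OPLS-DA on the
#' subset of samples in the pair, runs Welch tests per feature and applies
#' [selectDifferential()].
#'
#' @param table preprocessed feature table (no missing values).
#' @param pair character(2), groups compared (first over second).
#' @param nOrtho,scale passed to [fitOPLSDA()].
#' @param cv compute Q2 for the pair model (default FALSE; the screen only
#'   needs VIP).
#' @param ... passed to [selectDifferential()].
#' @return A list: `result` (the selection data frame), `model` (the
#'   [OplsModel-class]), `pair`.
#' @export
differentialScreen <- function(table, pair, nOrtho = 1, scale = TRUE,
                               cv = FALSE, ...) {
  groups <- sampleGroups(table)
  keep <- groups %in% pair
  sub <- table[, keep]
  model <- fitOPLSDA(sub, groups[keep], nOrtho = nOrtho, scale = scale,
                     cv = cv)
  tests <- welchPerFeature(sub, groups[keep], pair = pair)
  res <- selectDifferential(vipScores(model), tests$p_raw,
                            tests$log2_fold_change,
                            feature_id = tests$feature_id, ...)
  list(result = res, model = model, pair = pair)
}

#' Deterministic complete-linkage clustering order
#'
#' The row (or column) ordering used for heatmaps: per-feature z-scores
#' across samples (zero-variance features become all-zero rows, with a
#' message), Euclidean distances and complete-linkage agglomeration.
#'
#' @param m numeric matrix; items to order in rows.
#' @param zscore standardize rows first (default TRUE).
#' @return A list: `order` (integer leaf order), `labels`, `hclust` (the
#'   [stats::hclust] tree).
#' @export
heatmapOrder <- function(m, zscore = TRUE) {
  if (!is.matrix(m) || nrow(m) < 2L)
    stop("'m' must be a matrix with at least two rows")
  if (zscore) {
    mu <- rowMeans(m)
    s <- apply(m, 1L, stats::sd)
    zero <- s < .Machine$double.eps^0.5
    if (any(zero)) {
      message(sum(zero), " zero-variance row(s); z-scores set to 0")
      s[zero] <- 1
    }
    m <- sweep(sweep(m, 1L, mu), 1L, s, "/")
  }
  hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                      method = "complete")
  list(order = hc$order, labels = rownames(m), hclust = hc)
}
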
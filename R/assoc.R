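## Cross-omics association: Spearman correlation of VOCs against
## non-volatile metabolites, and hypergeometric pathway
## over-representation of selected features.

#' Spearman correlation matrix between two feature tables
#'
#' Pairwise Spearman rank correlation between every metabolite and every
#' VOC measured on the same samples (in the same order): the correlation
#' is the Pearson correlation of mid-ranks (average ranks for ties), the
#' p-value comes from the t approximation on `n - 2` degrees of freedom,
#' and optionally from the exact permutation distribution for small n.
#' Zero-variance columns give undefined correlations, reported as `NA`
#' with a warning.
#'
#' @param x_met samples x metabolites matrix or feature table.
#' @param x_voc samples x VOCs matrix or feature table, same samples in
#'   the same order.
#' @param p_threshold significance threshold on the raw p (default 0.05,
#'   the flagging convention of clustered double-matrix heatmaps);
#'   BH-adjusted p-values are also returned.
#' @param exact use the exact p-value for n <= 10 (delegates to
#'   [stats::cor.test]; requires untied data).
#' @return A list of matrices (`rho`, `p`, `p_adjusted`, `significant`)
#'   with metabolites in rows and VOCs in columns, plus `edges`, a
#'   long-format data frame (`metabolite`, `voc`, `rho`, `p`,
#'   `significant`).
#' @export
spearmanMatrix <- function(x_met, x_voc, p_threshold = 0.05, exact = FALSE) {
  a <- if (methods::is(x_met, "SummarizedExperiment"))
    intensityMatrix(x_met) else x_met
  b <- if (methods::is(x_voc, "SummarizedExperiment"))
    intensityMatrix(x_voc) else x_voc
  if (nrow(a) != nrow(b))
    stop("both tables must cover the same samples")
  if (!is.null(rownames(a)) && !is.null(rownames(b)) &&
      !identical(rownames(a), rownames(b)))
    stop("sample ids differ or are ordered differently")
  n <- nrow(a)
  if (n < 3L) stop("at least 3 samples required")
  const_a <- apply(a, 2L, function(v) length(unique(v)) == 1L)
  const_b <- apply(b, 2L, function(v) length(unique(v)) == 1L)
  if (any(const_a) || any(const_b))
    warning("zero-variance column(s); correlations reported as NA: ",
            paste(c(colnames(a)[const_a], colnames(b)[const_b]),
                  collapse = ", "))
  if (is.null(colnames(a))) colnames(a) <- paste0("met_", seq_len(ncol(a)))
  if (is.null(colnames(b))) colnames(b) <- paste0("voc_", seq_len(ncol(b)))
  ra <- apply(a, 2L, rank)
  rb <- apply(b, 2L, rank)
  rho <- suppressWarnings(stats::cor(ra, rb))
  rho[const_a, ] <- NA
  rho[, const_b] <- NA
  if (exact && n <= 10L) {
    p <- rho
    for (i in seq_len(ncol(a))) for (j in seq_len(ncol(b)))
      p[i, j] <- if (is.na(rho[i, j])) NA_real_ else
        stats::cor.test(a[, i], b[, j], method = "spearman",
                        exact = TRUE)$p.value
  } else {
    tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
  }
  p_adjusted <- p
  p_adjusted[!is.na(p)] <- bhAdjust(p[!is.na(p)])
  significant <- !is.na(p) & p < p_threshold
  edges <- data.frame(
    metabolite = rep(rownames(rho), ncol(rho)),
    voc = rep(colnames(rho), each = nrow(rho)),
    rho = as.vector(rho), p = as.vector(p),
    p_adjusted = as.vector(p_adjusted),
    significant = as.vector(significant))
  list(rho = rho, p = p, p_adjusted = p_adjusted,
       significant = significant, edges = edges)
}

#' Hypergeometric pathway over-representation
#'
#' Upper-tail hypergeometric test of each pathway's membership among the
#' selected features: with `N` features in the universe, `K` of them in
#' the pathway, `n` selected and `k` selected pathway members, the
#' p-value is `P(X >= k)` for `X` hypergeometric `(N, K, n)`. P-values
#' are BH-adjusted across pathways. Pathway members outside the declared
#' universe are ignored.
#'
#' @param selected character, selected feature ids (must be a subset of
#'   `universe`).
#' @param pathways named list mapping pathway id to member feature ids.
#' @param universe character, all feature ids eligible for selection.
#' @return Data frame with `pathway_id`, `hits`, `pathway_size`,
#'   `selected_size`, `universe_size`, `p`, `p_adjusted`, ordered by `p`.
#' @export
oraHypergeometric <- function(selected, pathways, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  selected <- unique(selected)
  if (!all(selected %in% universe))
    stop("selected features outside the universe: ",
         paste(utils::head(setdiff(selected, universe), 5), collapse = ", "))
  N <- length(universe)
  n <- length(selected)
  res <- lapply(names(pathways), function(pid) {
    members <- intersect(unique(pathways[[pid]]), universe)
    K <- length(members)
    k <- length(intersect(members, selected))
    p <- if (K == 0L) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway_id = pid, hits = k, pathway_size = K,
               selected_size = n, universe_size = N, p = p)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- bhAdjust(out$p)
  out[order(out$p, out$pathway_id), , drop = FALSE]
}
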
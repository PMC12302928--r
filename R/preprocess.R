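#' Quality-control thresholds
#'
#' Bundles the peak- and feature-level QC thresholds used throughout
#' preprocessing. Boundary semantics follow the conventions of
#' chromatography software reports: signal-to-noise and library similarity
#' are inclusive (`>=`), the missingness filter removes features with
#' *more than* `max_missing_frac` missing (a feature missing in exactly
#' half the samples is kept), and retention-index confirmation requires the
#' absolute deviation to be *strictly less than* `ri_tolerance`.
#'
#' @param min_sn minimum signal-to-noise ratio (inclusive).
#' @param min_similarity minimum spectral library match score, 0-999 scale
#'   (inclusive).
#' @param max_missing_frac maximum tolerated missing fraction per feature
#'   (strictly-greater values are removed).
#' @param ri_tolerance maximum absolute deviation between calculated and
#'   theoretical retention index (strict).
#' @return A list of class `QcThresholds`.
#' @export
qcThresholds <- function(min_sn = 50, min_similarity = 700,
                         max_missing_frac = 0.5, ri_tolerance = 20) {
  .assertScalarNumber(min_sn, "min_sn", lower = 0, strict_lower = TRUE)
  .assertScalarNumber(min_similarity, "min_similarity", lower = 0,
                      strict_lower = TRUE)
  .assertScalarNumber(max_missing_frac, "max_missing_frac", 0, 1,
                      strict_upper = TRUE)
  .assertScalarNumber(ri_tolerance, "ri_tolerance", lower = 0,
                      strict_lower = TRUE)
  structure(list(min_sn = min_sn, min_similarity = min_similarity,
                 max_missing_frac = max_missing_frac,
                 ri_tolerance = ri_tolerance),
            class = "QcThresholds")
}

#' Filter peaks on signal-to-noise and library similarity
#'
#' A peak is retained iff `signal_to_noise >= min_sn` and
#' `similarity >= min_similarity` (both inclusive). Every rejection is
#' reported with the criterion it failed.
#'
#' @param peaks data frame with columns `feature_id`, `signal_to_noise`,
#'   `similarity`.
#' @param thresholds a [qcThresholds()].
#' @return A list: `retained` (character feature ids) and `rejections`
#'   (data frame `feature_id`, `reason` in `"S/N"`, `"similarity"`,
#'   `"S/N+similarity"`).
#' @export
filterPeaks <- function(peaks, thresholds = qcThresholds()) {
  stopifnot(is.data.frame(peaks),
            all(c("feature_id", "signal_to_noise", "similarity") %in%
                  names(peaks)))
  if (nrow(peaks) == 0L) stop("'peaks' must contain at least one record")
  if (any(peaks$signal_to_noise < 0))
    stop("signal_to_noise must be non-negative")
  if (any(peaks$similarity < 0 | peaks$similarity > 999))
    stop("similarity must lie in [0, 999]")
  ok_sn <- peaks$signal_to_noise >= thresholds$min_sn
  ok_sim <- peaks$similarity >= thresholds$min_similarity
  keep <- ok_sn & ok_sim
  reason <- character(sum(!keep))
  reason[!ok_sn[!keep] & ok_sim[!keep]] <- "S/N"
  reason[ok_sn[!keep] & !ok_sim[!keep]] <- "similarity"
  reason[!ok_sn[!keep] & !ok_sim[!keep]] <- "S/N+similarity"
  list(retained = peaks$feature_id[keep],
       rejections = data.frame(feature_id = peaks$feature_id[!keep],
                               reason = reason))
}

#' Internal-standard normalization (semi-quantification)
#'
#' Divides every intensity in a sample by that sample's internal-standard
#' intensity, yielding relative content, then drops the internal-standard
#' channel (which would be identically 1). Applying the function twice is a
#' no-op beyond the first.
#'
#' @param table a feature table whose `internalStandard()` is set.
#' @return The normalized table without the internal-standard feature.
#' @export
normalizeInternalStandard <- function(table) {
  is_id <- internalStandard(table)
  if (is.null(is_id))
    stop("table has no internal-standard feature")
  m <- SummarizedExperiment::assay(table, "intensity")
  if (!is_id %in% rownames(m))
    stop("internal standard '", is_id, "' not found in the table")
  is_row <- m[is_id, ]
  bad <- is.na(is_row) | is_row <= 0
  if (any(bad))
    stop("internal-standard intensity missing or non-positive in sample(s): ",
         paste(colnames(m)[bad], collapse = ", "))
  m <- sweep(m, 2L, is_row, "/")
  m <- m[rownames(m) != is_id, , drop = FALSE]
  out <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = m),
    colData = SummarizedExperiment::colData(table),
    metadata = S4Vectors::metadata(table))
  S4Vectors::metadata(out)$internal_standard <- NULL
  S4Vectors::metadata(out)$normalized <- TRUE
  out
}

#' Missingness filter
#'
#' Removes features whose missing fraction strictly exceeds
#' `max_missing_frac`; a feature missing in exactly that fraction of
#' samples is kept.
#'
#' @param table a feature table.
#' @param max_missing_frac maximum tolerated missing fraction, default 0.5.
#' @return A list: `table` (filtered) and `removed` (character feature ids).
#' @export
filterMissingness <- function(table, max_missing_frac = 0.5) {
  .assertScalarNumber(max_missing_frac, "max_missing_frac", 0, 1,
                      strict_upper = TRUE)
  m <- SummarizedExperiment::assay(table, "intensity")
  frac <- rowMeans(is.na(m))
  drop <- frac > max_missing_frac
  list(table = table[!drop, ], removed = rownames(m)[drop])
}

#' Half-minimum imputation
#'
#' Replaces each missing cell by half the smallest observed value of that
#' feature — the conventional stand-in for intensities censored below the
#' detection limit.
#'
#' @param table a feature table with every feature observed in at least one
#'   sample.
#' @return The table with no missing cells.
#' @export
imputeHalfMin <- function(table) {
  m <- SummarizedExperiment::assay(table, "intensity")
  n_obs <- rowSums(!is.na(m))
  if (any(n_obs == 0L))
    stop("feature(s) with no observed values (run filterMissingness first): ",
         paste(rownames(m)[n_obs == 0L], collapse = ", "))
  for (i in which(rowSums(is.na(m)) > 0L)) {
    m[i, is.na(m[i, ])] <- min(m[i, ], na.rm = TRUE) / 2
  }
  SummarizedExperiment::assay(table, "intensity") <- m
  table
}

#' Retention index by van den Dool-Kratz interpolation
#'
#' Computes the temperature-programmed retention index of an analyte from
#' an n-alkane ladder: `RI = 100 * n + 100 * (t - t_n) / (t_{n+1} - t_n)`,
#' where `t_n <= t <= t_{n+1}` are the retention times of the alkanes with
#' `n` and `n + 1` carbons bracketing the analyte (for gapped ladders the
#' factor scales with the carbon gap). An alkane's own retention time maps
#' exactly to 100 times its carbon number. No extrapolation beyond the
#' ladder is performed.
#'
#' @param retention_time analyte retention time in minutes (scalar).
#' @param ladder data frame with strictly increasing `retention_time` and
#'   sorted `carbon_number` columns.
#' @return The dimensionless retention index.
#' @examples
#' ladder <- data.frame(carbon_number = 10:11, retention_time = c(10, 12))
#' computeRI(11, ladder)   # 1050
#' @export
computeRI <- function(retention_time, ladder) {
  stopifnot(is.data.frame(ladder),
            all(c("carbon_number", "retention_time") %in% names(ladder)))
  if (is.unsorted(ladder$carbon_number, strictly = TRUE))
    stop("ladder carbon numbers must be strictly increasing")
  if (is.unsorted(ladder$retention_time, strictly = TRUE))
    stop("ladder retention times must be strictly increasing")
  .assertScalarNumber(retention_time, "retention_time")
  rt <- ladder$retention_time
  cn <- ladder$carbon_number
  if (retention_time < rt[1] || retention_time > rt[length(rt)])
    stop(sprintf(
      "retention time %.4g outside the ladder span [%.4g, %.4g]",
      retention_time, rt[1], rt[length(rt)]))
  i <- findInterval(retention_time, rt, rightmost.closed = TRUE)
  if (retention_time == rt[i]) return(100 * cn[i])
  100 * cn[i] + (100 * (cn[i + 1] - cn[i])) *
    ((retention_time - rt[i]) / (rt[i + 1] - rt[i]))
}

#' Confirm compound identity by retention-index agreement
#'
#' An identification is confirmed iff the absolute difference between the
#' calculated and the theoretical retention index is strictly less than
#' `ri_tolerance`.
#'
#' @param calculated_ri,theoretical_ri finite retention indices (vectors
#'   recycle).
#' @param ri_tolerance strict tolerance, default 20.
#' @return Logical vector of confirmation flags.
#' @export
confirmIdentity <- function(calculated_ri, theoretical_ri, ri_tolerance = 20) {
  if (!all(is.finite(calculated_ri)) || !all(is.finite(theoretical_ri)))
    stop("retention indices must be finite")
  .assertScalarNumber(ri_tolerance, "ri_tolerance", lower = 0,
                      strict_lower = TRUE)
  abs(calculated_ri - theoretical_ri) < ri_tolerance
}

#' Run the full preprocessing chain
#'
#' Applies, in fixed order: peak QC filtering (if peak records are given),
#' retention-index identity confirmation (if annotations and a ladder are
#' given), internal-standard normalization, the missingness filter and
#' half-minimum imputation. Running the chain on its own output (with the
#' already-consumed inputs omitted) is a no-op.
#'
#' @param table a feature table.
#' @param thresholds a [qcThresholds()].
#' @param peaks optional peak record data frame (see [filterPeaks()]).
#' @param annotations optional VOC annotation data frame with
#'   `feature_id`, `theoretical_ri` and `retention_time` columns.
#' @param ladder optional alkane ladder for retention-index confirmation.
#' @param missingness_filter apply the missingness filter (default TRUE).
#' @return A list: `table` (preprocessed), `log` (data frame of per-stage
#'   feature counts), `removed` (named list of dropped feature ids per
#'   stage).
#' @export
preprocessTable <- function(table, thresholds = qcThresholds(),
                            peaks = NULL, annotations = NULL, ladder = NULL,
                            missingness_filter = TRUE) {
  removed <- list()
  log <- data.frame(stage = "input", n_features = nrow(table))
  add <- function(stage, tab) rbind(log, data.frame(stage = stage,
                                                    n_features = nrow(tab)))
  is_id <- internalStandard(table)
  if (!is.null(peaks)) {
    qc <- filterPeaks(peaks, thresholds)
    keep <- rownames(table) %in% c(qc$retained, is_id)
    removed$peak_qc <- rownames(table)[!keep]
    table <- table[keep, ]
    log <- add("peak_qc", table)
  }
  if (!is.null(annotations) && !is.null(ladder)) {
    ann <- annotations[annotations$feature_id %in% rownames(table), ]
    calc <- vapply(ann$retention_time, computeRI, numeric(1), ladder = ladder)
    ok <- confirmIdentity(calc, ann$theoretical_ri, thresholds$ri_tolerance)
    keep <- rownames(table) %in% c(ann$feature_id[ok], is_id)
    removed$ri_confirmation <- rownames(table)[!keep]
    table <- table[keep, ]
    log <- add("ri_confirmation", table)
  }
  if (!is.null(is_id)) {
    table <- normalizeInternalStandard(table)
    log <- add("is_normalization", table)
  }
  if (missingness_filter) {
    fm <- filterMissingness(table, thresholds$max_missing_frac)
    table <- fm$table
    removed$missingness <- fm$removed
    log <- add("missingness_filter", table)
  }
  table <- imputeHalfMin(table)
  log <- add("imputation", table)
  list(table = table, log = log, removed = removed)
}
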
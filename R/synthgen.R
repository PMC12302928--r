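#' Configuration for the synthetic-study generator
#'
#' Parameters of the simulated multi-group profiling study. Defaults mirror
#' a three-breed beef design with three biological replicates per breed and
#' multiplicative (log-normal) intensity noise. Planted group effects are
#' multiplicative folds on a known subset of features, recorded in the
#' returned ground truth so recovery can be scored exactly.
#'
#' @param n_groups number of sample groups (3 gives groups GL, SN, XZ).
#' @param n_per_group biological replicates per group (>= 2; use >= 20 for
#'   power studies).
#' @param n_metabolites,n_vocs number of features per table, excluding the
#'   internal-standard channel added to each.
#' @param frac_differential fraction of features per table planted with a
#'   group effect, in [0, 1].
#' @param effect_size multiplicative fold (> 1 means up in the affected
#'   group for direction +1) applied to planted features.
#' @param cv_noise coefficient of variation of the log-normal intensity
#'   noise; the log-scale standard deviation is `sqrt(log(1 + cv^2))`.
#' @param missing_rate fraction of cells masked missing-at-random, in [0, 1).
#' @param lod_quantile intensity quantile below which values are censored to
#'   missing (limit-of-detection structure), in [0, 1).
#' @param ladder_jitter_frac retention-time jitter of the alkane ladder as a
#'   fraction of the inter-alkane spacing (<= 0.01); 0 makes retention-index
#'   interpolation exactly affine.
#' @param seed integer seed; identical seeds give byte-identical studies.
#'
#' @return A validated list of class `SynthConfig`.
#' @seealso [generateStudy()]
#' @export
synthConfig <- function(n_groups = 3L, n_per_group = 3L,
                        n_metabolites = 200L, n_vocs = 150L,
                        frac_differential = 0.1, effect_size = 4,
                        cv_noise = 0.2, missing_rate = 0.05,
                        lod_quantile = 0.02, ladder_jitter_frac = 0,
                        seed = 1L) {
  .assertScalarNumber(n_groups, "n_groups", lower = 2)
  .assertScalarNumber(n_per_group, "n_per_group", lower = 2)
  .assertScalarNumber(n_metabolites, "n_metabolites", lower = 1)
  .assertScalarNumber(n_vocs, "n_vocs", lower = 1)
  .assertScalarNumber(frac_differential, "frac_differential", 0, 1)
  .assertScalarNumber(effect_size, "effect_size", lower = 0,
                      strict_lower = TRUE)
  .assertScalarNumber(cv_noise, "cv_noise", lower = 0, strict_lower = TRUE)
  .assertScalarNumber(missing_rate, "missing_rate", 0, 1, strict_upper = TRUE)
  .assertScalarNumber(lod_quantile, "lod_quantile", 0, 1, strict_upper = TRUE)
  .assertScalarNumber(ladder_jitter_frac, "ladder_jitter_frac", 0, 0.01)
  .assertScalarNumber(seed, "seed")
  structure(list(
    n_groups = as.integer(n_groups), n_per_group = as.integer(n_per_group),
    n_metabolites = as.integer(n_metabolites), n_vocs = as.integer(n_vocs),
    frac_differential = frac_differential, effect_size = effect_size,
    cv_noise = cv_noise, missing_rate = missing_rate,
    lod_quantile = lod_quantile, ladder_jitter_frac = ladder_jitter_frac,
    seed = as.integer(seed)
  ), class = "SynthConfig")
}

# run expr under a fixed seed, restoring the caller's RNG state afterwards
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.groupLabels <- function(n_groups) {
  if (n_groups == 3L) c("GL", "SN", "XZ") else paste0("G", seq_len(n_groups))
}

# sensory vocabulary (packaged static stand-in for an external flavor
# database); first six are the attributes the network module must support
.SENSORY_VOCAB <- c("sweet", "fruity", "green", "waxy", "ethereal", "floral",
                    "fatty", "buttery", "almond", "cucumber", "rose", "nuts",
                    "cocoa", "herbal")

.VOC_CLASSES <- c("hydrocarbons", "alcohols", "aldehydes", "esters",
                  "ketones", "others")

# one simulated intensity table on the latent (pre-normalization) scale
.simulateTable <- function(prefix, n_features, groups, config,
                           sample_loading) {
  n <- length(groups)
  feat_ids <- sprintf("%s_%03d", prefix, seq_len(n_features))
  mu <- rnorm(n_features, mean = log(1e5), sd = 1)
  sigma <- sqrt(log(1 + config$cv_noise^2))
  group_levels <- unique(groups)
  latent <- matrix(rep(mu, length(group_levels)), ncol = length(group_levels),
                   dimnames = list(feat_ids, group_levels))
  n_diff <- round(config$frac_differential * n_features)
  truth <- data.frame(feature_id = character(0), group = character(0),
                      direction = integer(0), fold = numeric(0))
  if (n_diff > 0) {
    planted <- sample(feat_ids, n_diff)
    affected <- sample(group_levels, n_diff, replace = TRUE)
    direction <- sample(c(-1L, 1L), n_diff, replace = TRUE)
    for (i in seq_len(n_diff))
      latent[planted[i], affected[i]] <-
        latent[planted[i], affected[i]] + direction[i] * log(config$effect_size)
    truth <- data.frame(feature_id = planted, group = affected,
                        direction = direction, fold = config$effect_size)
  }
  noise <- matrix(rnorm(n * n_features, sd = sigma), nrow = n)
  values <- exp(t(latent[, groups, drop = FALSE]) + noise)
  # internal-standard channel: fixed spiked amount, so it tracks only the
  # per-sample loading factor applied below
  is_id <- paste0(prefix, "_IS")
  values <- cbind(values, exp(rep(log(1e5), n)))
  colnames(values) <- c(feat_ids, is_id)
  values <- values * sample_loading
  rownames(values) <- names(groups)
  list(values = values, latent = latent, truth = truth,
       internal_standard = is_id)
}

#' Generate a complete synthetic study
#'
#' Simulates every input the analysis pipeline consumes: a metabolite and a
#' VOC feature table (log-normal intensities, per-sample loading factors
#' removed by internal-standard normalization, planted multiplicative group
#' effects, limit-of-detection censoring plus missing-at-random masking), a
#' per-compound VOC annotation table (chemical class, odor threshold in
#' water, theoretical retention index consistent with the ladder, 1-4
#' sensory descriptors), peak quality records (signal-to-noise, library
#' similarity, retention time), an n-alkane retention ladder, a pathway
#' membership database with planted enrichment, and a ground-truth record.
#'
#' @param config a [synthConfig()].
#' @return A list of class `SynthStudy` with elements `metabolites` and
#'   `vocs` (feature tables, see [featureTable()]), `annotations`, `peaks`,
#'   `ladder` (data frames), `pathways` (named list of feature-id vectors),
#'   `truth` (list: `differential` data frame with feature id / table /
#'   affected group / direction / fold, `group_means` latent log-scale mean
#'   matrices, `enriched_pathways`) and the echoed `config`.
#' @examples
#' study <- generateStudy(synthConfig(seed = 7))
#' dim(intensityMatrix(study$vocs))
#' head(study$truth$differential)
#' @export
generateStudy <- function(config = synthConfig()) {
  if (!inherits(config, "SynthConfig"))
    stop("'config' must be created by synthConfig()")
  .withSeed(config$seed, {
    groups <- rep(.groupLabels(config$n_groups), each = config$n_per_group)
    sample_ids <- sprintf("%s_%d", groups,
                          rep(seq_len(config$n_per_group), config$n_groups))
    names(groups) <- sample_ids
    # per-sample instrument loading, shared by analytes and the internal
    # standard within a table
    loading_met <- exp(rnorm(length(groups), sd = 0.1))
    loading_voc <- exp(rnorm(length(groups), sd = 0.1))

    met <- .simulateTable("MET", config$n_metabolites, groups, config,
                          loading_met)
    voc <- .simulateTable("VOC", config$n_vocs, groups, config, loading_voc)

    ladder <- .simulateLadder(config)
    annotations <- .simulateAnnotations(voc, ladder)
    peaks <- .simulatePeaks(voc, annotations, ladder)
    pathways <- .simulatePathways(met, config)

    met_tab <- featureTable(met$values, groups,
                            internalStandard = met$internal_standard,
                            kind = "metabolite")
    voc_tab <- featureTable(voc$values, groups,
                            internalStandard = voc$internal_standard,
                            kind = "voc")
    met_tab <- injectMissingness(met_tab, config$missing_rate,
                                 config$lod_quantile)
    voc_tab <- injectMissingness(voc_tab, config$missing_rate,
                                 config$lod_quantile)

    differential <- rbind(
      cbind(table = rep("metabolite", nrow(met$truth)), met$truth),
      cbind(table = rep("voc", nrow(voc$truth)), voc$truth))
    rownames(differential) <- NULL
    structure(list(
      metabolites = met_tab, vocs = voc_tab,
      annotations = annotations, peaks = peaks, ladder = ladder,
      pathways = pathways$db,
      truth = list(differential = differential,
                   group_means = list(metabolite = met$latent,
                                      voc = voc$latent),
                   pathway_assignments = pathways$assignments,
                   enriched_pathways = pathways$enriched),
      config = config
    ), class = "SynthStudy")
  })
}

.simulateLadder <- function(config) {
  carbon <- 7:30
  spacing <- 1.5
  rt <- 4 + spacing * (carbon - carbon[1])
  if (config$ladder_jitter_frac > 0) {
    # jitter <= 1% of spacing cannot break strict monotonicity
    rt <- rt + runif(length(rt), -1, 1) * config$ladder_jitter_frac * spacing
  }
  data.frame(carbon_number = carbon, retention_time = rt)
}

.simulateAnnotations <- function(voc, ladder) {
  ids <- rownames(voc$latent)
  n <- length(ids)
  rt <- runif(n, min(ladder$retention_time), max(ladder$retention_time))
  true_ri <- vapply(rt, computeRI, numeric(1), ladder = ladder)
  n_desc <- sample(1:4, n, replace = TRUE)
  descriptors <- vapply(n_desc, function(k)
    paste(sample(.SENSORY_VOCAB, k), collapse = ";"), character(1))
  data.frame(
    feature_id = ids,
    compound_name = paste0("compound-", sub("^VOC_", "", ids)),
    cas = ifelse(runif(n) < 0.8,
                 sprintf("%d-%02d-%d", sample(100:9999, n, replace = TRUE),
                         sample(0:99, n, replace = TRUE),
                         sample(0:9, n, replace = TRUE)), NA),
    chemical_class = sample(.VOC_CLASSES, n, replace = TRUE,
                            prob = c(0.2, 0.2, 0.2, 0.15, 0.1, 0.15)),
    theoretical_ri = true_ri + rnorm(n, sd = 3),
    odor_threshold = 10^runif(n, -3, 1),
    descriptors = descriptors,
    retention_time = rt
  )
}

.simulatePeaks <- function(voc, annotations, ladder) {
  ids <- c(rownames(voc$latent), voc$internal_standard)
  n <- length(ids)
  rt <- c(annotations$retention_time,
          mean(range(ladder$retention_time)))
  # most peaks comfortably clear the QC thresholds; a small tail fails
  sn <- 10^rnorm(n, mean = log10(500), sd = 0.6)
  sim <- pmin(999, round(850 - 150 * stats::rexp(n, rate = 2)))
  data.frame(feature_id = ids, retention_time = rt,
             signal_to_noise = sn, similarity = sim)
}

.simulatePathways <- function(met, config, n_pathways = 8L) {
  ids <- rownames(met$latent)
  path_ids <- sprintf("PW%02d", seq_len(n_pathways))
  planted <- met$truth$feature_id
  enriched <- path_ids[1:2]
  assignments <- stats::setNames(
    sample(path_ids, length(ids), replace = TRUE), ids)
  # concentrate planted metabolites in the enriched pathways
  if (length(planted))
    assignments[planted] <- sample(enriched, length(planted), replace = TRUE)
  db <- lapply(path_ids, function(p) unname(ids[assignments == p]))
  names(db) <- path_ids
  list(db = db, assignments = assignments, enriched = enriched)
}

#' Inject missing values into a feature table
#'
#' Applies limit-of-detection censoring (all intensities below the
#' `lod_quantile` quantile of the table's observed values become missing)
#' followed by missing-at-random masking at rate `missing_rate`. The
#' internal-standard channel is never masked.
#'
#' @param table a feature table ([featureTable()]).
#' @param missing_rate fraction of cells masked at random, in [0, 1).
#' @param lod_quantile censoring quantile, in [0, 1).
#' @param seed optional seed; if `NULL` the current RNG stream is used.
#' @return The table with `NA` in masked cells.
#' @export
injectMissingness <- function(table, missing_rate, lod_quantile,
                              seed = NULL) {
  .assertScalarNumber(missing_rate, "missing_rate", 0, 1, strict_upper = TRUE)
  .assertScalarNumber(lod_quantile, "lod_quantile", 0, 1, strict_upper = TRUE)
  run <- function() {
    m <- SummarizedExperiment::assay(table, "intensity")
    is_id <- internalStandard(table)
    target <- if (is.null(is_id)) rep(TRUE, nrow(m)) else
      rownames(m) != is_id
    sub <- m[target, , drop = FALSE]
    if (lod_quantile > 0) {
      lod <- stats::quantile(sub, lod_quantile, na.rm = TRUE)
      sub[sub < lod] <- NA
    }
    if (missing_rate > 0) {
      mask <- matrix(runif(length(sub)) < missing_rate, nrow = nrow(sub))
      sub[mask] <- NA
    }
    m[target, ] <- sub
    SummarizedExperiment::assay(table, "intensity") <- m
    table
  }
  if (is.null(seed)) run() else .withSeed(seed, run())
}

#' @export
print.SynthStudy <- function(x, ...) {
  cat("SynthStudy:", ncol(x$metabolites), "samples in",
      length(unique(sampleGroups(x$metabolites))), "groups\n")
  cat("  metabolites:", nrow(x$metabolites), " vocs:", nrow(x$vocs), "\n")
  cat("  planted differential features:", nrow(x$truth$differential), "\n")
  invisible(x)
}
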
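## End-to-end orchestration: simulate (or read) -> preprocess ->
## chemometrics -> differential screen -> ROAV -> sensory network ->
## correlation -> enrichment, with every output written as schema-stamped
## CSV and a machine-readable manifest. Outputs are pure functions of
## (inputs, config, seed); reruns are byte-identical.

#' Pipeline run configuration
#'
#' Collects every tunable of the pipeline: the synthetic-study
#' configuration (used when `simulate = TRUE`), input paths (used
#' otherwise), QC thresholds and the screening/scoring parameters. All
#' analysis thresholds are explicit config keys.
#'
#' @param out_dir output directory (created if needed).
#' @param simulate generate the study with [generateStudy()] instead of
#'   reading input files.
#' @param synth a [synthConfig()]; its seed drives all randomness.
#' @param inputs named list of paths (`metabolites`, `vocs`,
#'   `annotations`, `ladder`, `pathways`, optionally `peaks`) when
#'   `simulate = FALSE`.
#' @param qc a [qcThresholds()].
#' @param vip_threshold,p_threshold,use_adjusted screening rule, see
#'   [selectDifferential()].
#' @param n_ortho orthogonal components for the pairwise OPLS-DA models.
#' @param top_k sensory attributes retained in the network.
#' @return A list of class `RunConfig`.
#' @export
runConfig <- function(out_dir, simulate = TRUE, synth = synthConfig(),
                      inputs = list(), qc = qcThresholds(),
                      vip_threshold = 1, p_threshold = 0.05,
                      use_adjusted = FALSE, n_ortho = 1, top_k = 10) {
  stopifnot(is.character(out_dir), length(out_dir) == 1L)
  if (!simulate) {
    need <- c("metabolites", "vocs", "annotations", "ladder", "pathways")
    miss <- setdiff(need, names(inputs))
    if (length(miss))
      stop("simulate = FALSE requires input path(s): ",
           paste(miss, collapse = ", "))
  }
  structure(list(out_dir = out_dir, simulate = simulate, synth = synth,
                 inputs = inputs, qc = qc, vip_threshold = vip_threshold,
                 p_threshold = p_threshold, use_adjusted = use_adjusted,
                 n_ortho = n_ortho, top_k = top_k),
            class = "RunConfig")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full pipeline
#'
#' Executes every stage in fixed order and writes per-stage CSV outputs
#' plus `manifest.json` (config echo, seed, stage order, per-stage record
#' counts and MD5 checksums of every written file) into
#' `config$out_dir`. Rerunning with the same config reproduces every file
#' byte for byte.
#'
#' @param config a [runConfig()].
#' @return The manifest, invisibly.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outfile <- function(...) file.path(config$out_dir, paste0(...))
  counts <- list()
  stages <- character(0)
  note <- function(stage, n) {
    stages <<- c(stages, stage)
    counts[[stage]] <<- n
  }

  study <- .stage("input", {
    if (config$simulate) {
      generateStudy(config$synth)
    } else {
      for (p in unlist(config$inputs))
        if (!file.exists(p)) stop("input file not found: ", p)
      list(metabolites = readFeatureTable(config$inputs$metabolites),
           vocs = readFeatureTable(config$inputs$vocs),
           annotations = readAnnotations(config$inputs$annotations),
           ladder = readLadder(config$inputs$ladder),
           pathways = readPathways(config$inputs$pathways),
           peaks = if (!is.null(config$inputs$peaks))
             .readSchemaCSV(config$inputs$peaks, "peaks") else NULL,
           truth = NULL)
    }
  })
  note("input", c(metabolites = nrow(study$metabolites),
                  vocs = nrow(study$vocs)))

  prep <- .stage("preprocess", {
    met <- preprocessTable(study$metabolites, config$qc)
    voc <- preprocessTable(study$vocs, config$qc, peaks = study$peaks,
                           annotations = study$annotations,
                           ladder = study$ladder)
    writeFeatureTable(met$table, outfile("metabolites_preprocessed.csv"))
    writeFeatureTable(voc$table, outfile("vocs_preprocessed.csv"))
    list(met = met$table, voc = voc$table,
         log = rbind(cbind(table = "metabolite", met$log),
                     cbind(table = "voc", voc$log)))
  })
  utils::write.csv(prep$log, outfile("preprocess_log.csv"),
                   row.names = FALSE)
  note("preprocess", c(metabolites = nrow(prep$met),
                       vocs = nrow(prep$voc)))

  pca <- .stage("chemometrics", {
    lapply(list(metabolites = prep$met, vocs = prep$voc), function(tab)
      fitPCA(tab, k = 2))
  })
  for (nm in names(pca)) {
    sc <- data.frame(sample_id = rownames(modelScores(pca[[nm]])),
                     modelScores(pca[[nm]]), check.names = FALSE)
    utils::write.csv(sc, outfile("pca_scores_", nm, ".csv"),
                     row.names = FALSE)
  }
  note("chemometrics",
       vapply(pca, function(m) round(100 * explainedVariance(m)[1], 2),
              numeric(1)))

  groups <- unique(sampleGroups(prep$met))
  pairs <- utils::combn(sort(groups), 2, simplify = FALSE)
  diff <- .stage("diff", {
    out <- list()
    for (tab_nm in c("metabolites", "vocs")) {
      tab <- if (tab_nm == "metabolites") prep$met else prep$voc
      for (pr in pairs) {
        scr <- differentialScreen(tab, pr, nOrtho = config$n_ortho,
                                  vip_threshold = config$vip_threshold,
                                  p_threshold = config$p_threshold,
                                  use_adjusted = config$use_adjusted)
        key <- paste0(tab_nm, "_", pr[1], "_vs_", pr[2])
        utils::write.csv(scr$result, outfile("diff_", key, ".csv"),
                         row.names = FALSE)
        out[[key]] <- scr
      }
    }
    out
  })
  note("diff", vapply(diff, function(d) sum(d$result$selected),
                      numeric(1)))

  roav <- .stage("roav", {
    out <- lapply(groups, function(g)
      computeROAV(prep$voc, study$annotations, group = g))
    names(out) <- groups
    for (g in groups)
      .writeSchemaCSV(out[[g]], outfile("roav_", g, ".csv"), "roav")
    comp <- classComposition(prep$voc, study$annotations)
    utils::write.csv(data.frame(chemical_class = rownames(comp), comp,
                                check.names = FALSE),
                     outfile("class_composition.csv"), row.names = FALSE)
    # per-group detection (observed pre-imputation in >= 1 sample)
    raw <- intensityMatrix(study$vocs)
    g_all <- sampleGroups(study$vocs)
    pres <- lapply(groups, function(g) {
      obs <- colSums(!is.na(raw[g_all == g, , drop = FALSE])) > 0
      intersect(colnames(raw)[obs], featureIds(prep$voc))
    })
    names(pres) <- groups
    if (length(groups) == 3L) {
      venn <- vennPartition(pres[sort(groups)])
      utils::write.csv(data.frame(region = names(venn), count = venn),
                       outfile("venn_regions.csv"), row.names = FALSE)
    }
    out
  })
  note("roav", vapply(roav, function(r)
    sum(!is.na(r$roav) & r$roav > 1), numeric(1)))

  network <- .stage("network", {
    sel_voc <- sort(unique(unlist(lapply(
      diff[grepl("^vocs_", names(diff))],
      function(d) d$result$feature_id[d$result$selected]))))
    net <- buildSensoryNetwork(sel_voc, study$annotations,
                               top_k = config$top_k)
    utils::write.csv(net$edges, outfile("network_edges.csv"),
                     row.names = FALSE)
    utils::write.csv(net$attributes, outfile("network_attributes.csv"),
                     row.names = FALSE)
    net
  })
  note("network", c(edges = nrow(network$edges),
                    attributes = nrow(network$attributes)))

  correlate <- .stage("correlate", {
    sel_met <- sort(unique(unlist(lapply(
      diff[grepl("^metabolites_", names(diff))],
      function(d) d$result$feature_id[d$result$selected]))))
    sel_voc <- unique(network$edges$voc)
    if (length(sel_met) < 1L || length(sel_voc) < 1L) {
      NULL
    } else {
      cm <- spearmanMatrix(intensityMatrix(prep$met)[, sel_met,
                                                     drop = FALSE],
                           intensityMatrix(prep$voc)[, sel_voc,
                                                     drop = FALSE])
      utils::write.csv(cm$edges, outfile("correlation_edges.csv"),
                       row.names = FALSE)
      cm
    }
  })
  note("correlate",
       if (is.null(correlate)) 0 else sum(correlate$significant))

  enrich <- .stage("enrich", {
    sel_met <- sort(unique(unlist(lapply(
      diff[grepl("^metabolites_", names(diff))],
      function(d) d$result$feature_id[d$result$selected]))))
    universe <- featureIds(prep$met)
    res <- oraHypergeometric(intersect(sel_met, universe),
                             study$pathways, universe)
    utils::write.csv(res, outfile("enrichment.csv"), row.names = FALSE)
    res
  })
  note("enrich", sum(enrich$p_adjusted < 0.05))

  files <- sort(list.files(config$out_dir, full.names = TRUE,
                           pattern = "\\.(csv|json)$"))
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    package = "flavoromics",
    version = as.character(utils::packageVersion("flavoromics")),
    schema = .FLAVOROMICS_SCHEMA,
    seed = config$synth$seed,
    config = .configEcho(config),
    stage_order = stages,
    counts = counts,
    checksums = as.list(tools::md5sum(files))
  )
  names(manifest$checksums) <- basename(files)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# config echo for the manifest, with classes flattened to plain lists
.configEcho <- function(config) {
  flat <- unclass(config)
  flat$synth <- unclass(flat$synth)
  flat$qc <- unclass(flat$qc)
  flat$out_dir <- NULL
  flat
}
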
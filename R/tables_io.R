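## File-to-file interface: quoted CSV with a schema version line and JSON
## sidecars. Readers validate strictly and reject malformed input rather
## than coercing; missing measurements are empty cells, never 0.

.writeSchemaCSV <- function(df, path, kind) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# %s %s", .FLAVOROMICS_SCHEMA, kind), con)
  utils::write.csv(df, con, row.names = FALSE, na = "")
}

.readSchemaCSV <- function(path, kind) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  skip <- 0L
  if (startsWith(first, "#")) {
    if (!grepl(.FLAVOROMICS_SCHEMA, first, fixed = TRUE))
      stop("unrecognized schema line in ", path, ": ", first)
    skip <- 1L
  }
  utils::read.csv(path, skip = skip, check.names = FALSE,
                  na.strings = "", stringsAsFactors = FALSE)
}

#' Read and write feature tables
#'
#' The on-disk format is a quoted CSV (schema version line, then a header
#' row) with one sample per row: `sample_id`, `group`, then one column per
#' feature. Missing measurements are empty cells. A JSON sidecar records
#' the schema, the table kind and the internal-standard feature id.
#' Writing then reading a table reproduces it up to floating-point
#' formatting.
#'
#' @param path CSV path.
#' @param metadata_path JSON sidecar path, default `<path>.json`.
#' @return `readFeatureTable` returns a feature table (see
#'   [featureTable()]); `writeFeatureTable` invisibly returns `path`.
#' @export
readFeatureTable <- function(path, metadata_path = paste0(path, ".json")) {
  df <- .readSchemaCSV(path, "feature-table")
  if (!all(c("sample_id", "group") %in% names(df)))
    stop("feature table must have 'sample_id' and 'group' columns")
  feat_cols <- names(df)[!names(df) %in% c("sample_id", "group")]
  if (length(feat_cols) == 0L) stop("no feature columns in ", path)
  dup_f <- unique(feat_cols[duplicated(feat_cols)])
  if (length(dup_f))
    stop("duplicate feature id(s): ", paste(dup_f, collapse = ", "))
  dup_s <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup_s))
    stop("duplicate sample id(s): ", paste(dup_s, collapse = ", "))
  m <- as.matrix(df[, feat_cols, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric intensity values in ", path)
  rownames(m) <- df$sample_id
  meta <- list(internal_standard = NULL, kind = "feature")
  if (file.exists(metadata_path)) {
    meta_in <- jsonlite::read_json(metadata_path, simplifyVector = TRUE)
    meta <- utils::modifyList(meta, meta_in[!vapply(meta_in, is.null,
                                                    logical(1))])
  }
  n_missing <- sum(is.na(m))
  if (n_missing)
    message(n_missing, " missing cell(s) in ", basename(path))
  featureTable(m, groups = df$group,
               internalStandard = meta$internal_standard, kind = meta$kind)
}

#' @rdname readFeatureTable
#' @param table a feature table.
#' @export
writeFeatureTable <- function(table, path,
                              metadata_path = paste0(path, ".json")) {
  m <- intensityMatrix(table)
  df <- data.frame(sample_id = rownames(m),
                   group = unname(sampleGroups(table)),
                   m, check.names = FALSE)
  .writeSchemaCSV(df, path, "feature-table")
  jsonlite::write_json(
    list(schema = .FLAVOROMICS_SCHEMA,
         kind = S4Vectors::metadata(table)$kind,
         internal_standard = internalStandard(table),
         n_samples = nrow(m), n_features = ncol(m),
         n_missing = sum(is.na(m))),
    metadata_path, auto_unbox = TRUE, null = "null", pretty = TRUE)
  invisible(path)
}

#' Read and write VOC annotations
#'
#' Columns: `feature_id`, `compound_name`, `cas` (optional), the closed
#' `chemical_class` vocabulary (hydrocarbons, alcohols, aldehydes, esters,
#' ketones, others), `theoretical_ri`, `odor_threshold` (same units as the
#' relative contents; must be positive where present), `descriptors`
#' (`;`-separated sensory attributes) and optionally `retention_time`.
#' Compound names with commas or Greek letters survive the quoted CSV
#' round trip.
#'
#' @param path CSV path.
#' @return A data frame of annotations.
#' @export
readAnnotations <- function(path) {
  df <- .readSchemaCSV(path, "voc-annotations")
  need <- c("feature_id", "compound_name", "chemical_class",
            "theoretical_ri", "odor_threshold", "descriptors")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("annotation file lacks column(s): ", paste(miss, collapse = ", "))
  dup <- unique(df$feature_id[duplicated(df$feature_id)])
  if (length(dup))
    stop("duplicate feature id(s): ", paste(dup, collapse = ", "))
  df$theoretical_ri <- as.numeric(df$theoretical_ri)
  df$odor_threshold <- as.numeric(df$odor_threshold)
  bad_ot <- !is.na(df$odor_threshold) & df$odor_threshold <= 0
  if (any(bad_ot))
    stop("non-positive odor threshold for: ",
         paste(df$feature_id[bad_ot], collapse = ", "))
  bad_cls <- !df$chemical_class %in% .VOC_CLASSES
  if (any(bad_cls))
    stop("chemical class outside the closed vocabulary for: ",
         paste(df$feature_id[bad_cls], collapse = ", "))
  df
}

#' @rdname readAnnotations
#' @param annotations annotation data frame.
#' @export
writeAnnotations <- function(annotations, path) {
  .writeSchemaCSV(annotations, path, "voc-annotations")
  invisible(path)
}

#' Read and write an n-alkane retention ladder
#'
#' Columns `carbon_number` (integers >= 5, strictly increasing, gaps
#' allowed) and `retention_time` (minutes, strictly increasing).
#'
#' @param path CSV path.
#' @return Ladder data frame.
#' @export
readLadder <- function(path) {
  df <- .readSchemaCSV(path, "alkane-ladder")
  if (!all(c("carbon_number", "retention_time") %in% names(df)))
    stop("ladder must have 'carbon_number' and 'retention_time' columns")
  if (any(df$carbon_number < 5))
    stop("carbon numbers below 5 in the ladder")
  if (is.unsorted(df$carbon_number, strictly = TRUE))
    stop("ladder carbon numbers must be strictly increasing")
  if (is.unsorted(df$retention_time, strictly = TRUE))
    stop("ladder retention times must be strictly increasing")
  df
}

#' @rdname readLadder
#' @param ladder ladder data frame.
#' @export
writeLadder <- function(ladder, path) {
  .writeSchemaCSV(ladder, path, "alkane-ladder")
  invisible(path)
}

#' Read and write a pathway membership table
#'
#' Long-format CSV with columns `pathway_id` and `feature_id`. Because
#' the analysis universe is declared separately, members unknown to an
#' optional `known_features` set raise a warning but are kept.
#'
#' @param path CSV path.
#' @param known_features optional character vector of recognized feature
#'   ids.
#' @return Named list mapping pathway id to member feature ids.
#' @export
readPathways <- function(path, known_features = NULL) {
  df <- .readSchemaCSV(path, "pathways")
  if (!all(c("pathway_id", "feature_id") %in% names(df)))
    stop("pathway file must have 'pathway_id' and 'feature_id' columns")
  if (!is.null(known_features)) {
    unknown <- setdiff(df$feature_id, known_features)
    if (length(unknown))
      warning(length(unknown), " pathway member(s) not among known ",
              "features (kept): ",
              paste(utils::head(unknown, 5), collapse = ", "))
  }
  split(df$feature_id, df$pathway_id)
}

#' @rdname readPathways
#' @param pathways named list of pathway memberships.
#' @export
writePathways <- function(pathways, path) {
  df <- data.frame(pathway_id = rep(names(pathways), lengths(pathways)),
                   feature_id = unlist(pathways, use.names = FALSE))
  .writeSchemaCSV(df, path, "pathways")
  invisible(path)
}
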
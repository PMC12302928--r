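#' Construct a feature table
#'
#' Builds the package's central container for a sample x feature intensity
#' matrix: a [SummarizedExperiment::SummarizedExperiment] with features as
#' rows, an `intensity` assay, per-sample group labels in `colData` and the
#' internal-standard feature id (if any) in `metadata`. Missing measurements
#' are `NA`; zero is a legal intensity and is never treated as missing.
#'
#' @param values numeric matrix, samples in rows and features in columns
#'   (the orientation of the delimited file format). Dimnames supply sample
#'   and feature ids.
#' @param groups character or factor, one group label per sample.
#' @param internalStandard optional feature id of the internal-standard
#'   channel (spiked reference used for semi-quantification).
#' @param kind free-text tag, conventionally `"metabolite"` or `"voc"`.
#'
#' @return A `SummarizedExperiment` (features x samples).
#' @examples
#' m <- matrix(rlnorm(12), 3, 4,
#'             dimnames = list(paste0("S", 1:3), paste0("F", 1:4)))
#' ft <- featureTable(m, groups = c("GL", "SN", "XZ"))
#' @export
featureTable <- function(values, groups, internalStandard = NULL,
                         kind = "feature") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (samples x features)")
  if (is.null(rownames(values)))
    rownames(values) <- paste0("sample_", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("feature_", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate feature ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (length(groups) != nrow(values))
    stop("'groups' must have one label per sample (",
         nrow(values), " samples, ", length(groups), " labels)")
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop(sprintf("negative intensity at sample '%s', feature '%s'",
                 rownames(values)[neg[1, 1]], colnames(values)[neg[1, 2]]))
  if (!is.null(internalStandard) && !internalStandard %in% colnames(values))
    stop("internal standard '", internalStandard,
         "' is not a feature of the table")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = t(values)),
    colData = S4Vectors::DataFrame(group = as.character(groups),
                                   row.names = rownames(values)),
    metadata = list(internal_standard = internalStandard, kind = kind)
  )
}

#' @rdname featureTable
#' @param x a feature table.
#' @export
intensityMatrix <- function(x) t(SummarizedExperiment::assay(x, "intensity"))

#' @rdname featureTable
#' @export
sampleGroups <- function(x) {
  g <- SummarizedExperiment::colData(x)$group
  stats::setNames(as.character(g), colnames(x))
}

#' @rdname featureTable
#' @export
featureIds <- function(x) rownames(x)

#' @rdname featureTable
#' @export
sampleIds <- function(x) colnames(x)

#' @rdname featureTable
#' @export
internalStandard <- function(x) S4Vectors::metadata(x)$internal_standard
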
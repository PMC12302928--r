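## Aroma-contribution scoring and descriptive summaries of the VOC table:
## OAV / ROAV, contribution classes, chemical-class composition, Venn
## partition of per-group detection, and the VOC-sensory bipartite network.

#' Relative odor activity values (ROAV)
#'
#' Scores each compound's contribution to the aroma profile of one group:
#' the odor activity value is the group-mean relative content divided by
#' the compound's odor threshold in water, `OAV_i = C_i / OT_i`, and the
#' relative odor activity value rescales to the group's strongest
#' compound, `ROAV_i = 100 * OAV_i / OAV_max`, so ROAV lies on a 0-100
#' scale and at least one compound scores exactly 100. Compounds without
#' an odor threshold are listed unscored and never determine `OAV_max`.
#' Contribution classes: `key` for ROAV strictly above 1, `moderate` for
#' ROAV in the closed interval [0.1, 1], `minor` below 0.1.
#'
#' @param contents named numeric vector of mean relative contents `C_i`
#'   for one group (see [groupMeanContents()]), or a feature table from
#'   which per-group means are taken.
#' @param annotations VOC annotation data frame with `feature_id` and
#'   `odor_threshold` columns.
#' @param group when `contents` is a feature table: the group to score.
#' @param aggregate group aggregation, `"mean"` (default) or `"median"`.
#' @return Data frame with `feature_id`, `content`, `odor_threshold`,
#'   `oav`, `roav`, `contribution_class` (`NA` rows for compounds without
#'   a threshold).
#' @export
computeROAV <- function(contents, annotations, group = NULL,
                        aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  if (methods::is(contents, "SummarizedExperiment")) {
    if (is.null(group)) stop("'group' is required with a feature table")
    contents <- groupMeanContents(contents, aggregate)[, group]
  }
  if (is.null(names(contents)))
    stop("'contents' must be named by feature id")
  if (any(contents < 0, na.rm = TRUE)) stop("contents must be non-negative")
  ot <- annotations$odor_threshold[match(names(contents),
                                         annotations$feature_id)]
  if (any(!is.na(ot) & ot <= 0)) stop("odor thresholds must be positive")
  oav <- ifelse(is.na(ot), NA_real_, contents / ot)
  scored <- !is.na(oav)
  if (!any(scored)) stop("no compound carries an odor threshold")
  oav_max <- max(oav[scored])
  if (oav_max <= 0)
    stop("all odor activity values are zero; no reference compound")
  roav <- 100 * oav / oav_max
  data.frame(feature_id = names(contents), content = unname(contents),
             odor_threshold = ot, oav = unname(oav), roav = unname(roav),
             contribution_class = classifyContribution(roav),
             row.names = NULL)
}

#' @rdname computeROAV
#' @param roav numeric ROAV values on the 0-100 scale.
#' @export
classifyContribution <- function(roav) {
  ifelse(is.na(roav), NA_character_,
         ifelse(roav > 1, "key",
                ifelse(roav >= 0.1, "moderate", "minor")))
}

#' Per-group mean relative contents
#'
#' @param table a feature table.
#' @param aggregate `"mean"` or `"median"` across the group's samples.
#' @return features x groups matrix of aggregated contents.
#' @export
groupMeanContents <- function(table, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  m <- intensityMatrix(table)
  g <- sampleGroups(table)
  fun <- if (aggregate == "mean") colMeans else
    function(x) apply(x, 2L, stats::median)
  out <- vapply(unique(g), function(lv) fun(m[g == lv, , drop = FALSE]),
                numeric(ncol(m)))
  rownames(out) <- colnames(m)
  out
}

#' Relative content composition by chemical class
#'
#' For each group, sums the mean relative contents of its features within
#' each chemical class and expresses them as percentages of the group
#' total (summing to 100). Features without a class annotation are
#' assigned to `"others"` with a warning.
#'
#' @param table a feature table.
#' @param annotations annotation data frame with `feature_id` and
#'   `chemical_class`.
#' @return classes x groups matrix of percentages.
#' @export
classComposition <- function(table, annotations) {
  means <- groupMeanContents(table)
  cls <- annotations$chemical_class[match(rownames(means),
                                          annotations$feature_id)]
  if (anyNA(cls)) {
    warning(sum(is.na(cls)), " unannotated feature(s) assigned to 'others'")
    cls[is.na(cls)] <- "others"
  }
  sums <- rowsum(means, cls)
  sweep(sums, 2L, colSums(sums), "/") * 100
}

#' Three-set Venn partition
#'
#' Counts the seven exclusive regions of three feature sets (per-group
#' detections). The regions are pairwise disjoint and their counts sum to
#' the size of the union.
#'
#' @param sets named list of three character vectors.
#' @return Named integer vector over the regions `A`, `B`, `C`, `AB`,
#'   `AC`, `BC`, `ABC` (only-in labels, using the list names).
#' @export
vennPartition <- function(sets) {
  if (length(sets) != 3L) stop("exactly three sets required")
  if (is.null(names(sets))) names(sets) <- c("A", "B", "C")
  sets <- lapply(sets, unique)
  u <- unique(unlist(sets))
  member <- vapply(sets, function(s) u %in% s, logical(length(u)))
  if (length(u) == 0L)
    member <- matrix(logical(0), 0, 3, dimnames = list(NULL, names(sets)))
  key <- member %*% c(1L, 2L, 4L)
  nm <- names(sets)
  regions <- c(1, 2, 4, 3, 5, 6, 7)
  labels <- c(nm, paste0(nm[1], ":", nm[2]), paste0(nm[1], ":", nm[3]),
              paste0(nm[2], ":", nm[3]), paste(nm, collapse = ":"))
  counts <- vapply(regions, function(r) sum(key == r), integer(1))
  stats::setNames(counts, labels)
}

#' VOC-sensory attribute bipartite network
#'
#' Builds the bipartite graph linking selected VOCs to their sensory
#' descriptors, keeps only the `top_k` attributes by degree (number of
#' incident VOCs; ties broken lexicographically) and annotates node
#' degrees. Attribute retention is invariant to the order of the input
#' VOC ids.
#'
#' @param voc_ids character, the selected VOC feature ids.
#' @param annotations annotation data frame with `feature_id` and a
#'   `descriptors` column (`;`-separated descriptor strings or a list
#'   column).
#' @param top_k number of sensory attributes retained, default 10.
#' @return A list: `edges` (data frame `voc`, `attribute`), `attributes`
#'   (data frame `attribute`, `degree`, retained ones only), `vocs`
#'   (data frame `voc`, `degree` within the retained network) and `graph`
#'   (an [igraph::graph] with a logical `type` vertex attribute, TRUE for
#'   attributes).
#' @export
buildSensoryNetwork <- function(voc_ids, annotations, top_k = 10) {
  .assertScalarNumber(top_k, "top_k", lower = 1)
  idx <- match(voc_ids, annotations$feature_id)
  if (anyNA(idx))
    stop("unannotated VOC id(s): ",
         paste(voc_ids[is.na(idx)], collapse = ", "))
  desc <- annotations$descriptors[idx]
  desc <- if (is.list(desc)) desc else strsplit(as.character(desc), ";",
                                                fixed = TRUE)
  edges <- data.frame(
    voc = rep(voc_ids, lengths(desc)),
    attribute = trimws(unlist(desc, use.names = FALSE)))
  edges <- edges[nzchar(edges$attribute), , drop = FALSE]
  edges <- unique(edges)
  if (nrow(edges) == 0L) {
    warning("no sensory descriptors among the selected VOCs; empty network")
    return(list(edges = edges,
                attributes = data.frame(attribute = character(0),
                                        degree = integer(0)),
                vocs = data.frame(voc = character(0), degree = integer(0)),
                graph = igraph::make_empty_graph(directed = FALSE)))
  }
  deg <- table(edges$attribute)
  rank <- order(-as.integer(deg), names(deg))
  keep_attr <- names(deg)[rank][seq_len(min(top_k, length(deg)))]
  edges <- edges[edges$attribute %in% keep_attr, , drop = FALSE]
  rownames(edges) <- NULL
  attributes <- data.frame(attribute = keep_attr,
                           degree = as.integer(deg[keep_attr]))
  voc_deg <- table(edges$voc)
  vocs <- data.frame(voc = names(voc_deg), degree = as.integer(voc_deg))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::V(g)$type <- igraph::V(g)$name %in% keep_attr
  list(edges = edges, attributes = attributes, vocs = vocs, graph = g)
}
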
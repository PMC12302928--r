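#' @name flavoromics-accessors
#' @title Accessors for fitted chemometric models
#'
#' @description Accessor generics for [PcaModel-class] and [OplsModel-class]
#' objects: sample scores, feature loadings, per-component explained-variance
#' fractions, VIP scores and the R2Y / Q2 model-quality statistics.
#'
#' @param object a fitted model.
#' @return `modelScores` and `modelLoadings` return matrices (predictive
#'   component first for OPLS-DA); `explainedVariance` a numeric vector;
#'   `vipScores` a named numeric vector; `r2y` and `q2` single numbers.
NULL

#' @rdname flavoromics-accessors
#' @export
setGeneric("modelScores", function(object) standardGeneric("modelScores"))

#' @rdname flavoromics-accessors
#' @export
setGeneric("modelLoadings", function(object) standardGeneric("modelLoadings"))

#' @rdname flavoromics-accessors
#' @export
setGeneric("explainedVariance",
           function(object) standardGeneric("explainedVariance"))

#' @rdname flavoromics-accessors
#' @export
setGeneric("vipScores", function(object) standardGeneric("vipScores"))

#' @rdname flavoromics-accessors
#' @export
setGeneric("r2y", function(object) standardGeneric("r2y"))

#' @rdname flavoromics-accessors
#' @export
setGeneric("q2", function(object) standardGeneric("q2"))

#' @rdname flavoromics-accessors
#' @export
setMethod("modelScores", "PcaModel", function(object) object@scores)

#' @rdname flavoromics-accessors
#' @export
setMethod("modelLoadings", "PcaModel", function(object) object@loadings)

#' @rdname flavoromics-accessors
#' @export
setMethod("explainedVariance", "PcaModel",
          function(object) object@explainedVariance)

#' @rdname flavoromics-accessors
#' @export
setMethod("modelScores", "OplsModel", function(object) {
  cbind(predictive = object@scores, object@orthoScores)
})

#' @rdname flavoromics-accessors
#' @export
setMethod("modelLoadings", "OplsModel", function(object) {
  cbind(predictive = object@loadings, object@orthoLoadings)
})

#' @rdname flavoromics-accessors
#' @export
setMethod("vipScores", "OplsModel", function(object) object@vip)

#' @rdname flavoromics-accessors
#' @export
setMethod("r2y", "OplsModel", function(object) object@r2y)

#' @rdname flavoromics-accessors
#' @export
setMethod("q2", "OplsModel", function(object) object@q2)

setMethod("show", "PcaModel", function(object) {
  cat("PcaModel:", nrow(object@scores), "samples,",
      nrow(object@loadings), "features,",
      ncol(object@scores), "components\n")
  ev <- round(100 * object@explainedVariance, 2)
  cat("  explained variance (%):", paste(ev, collapse = ", "), "\n")
})

setMethod("show", "OplsModel", function(object) {
  cat("OplsModel:", object@classes[1], "vs", object@classes[2],
      sprintf("(1 predictive + %d orthogonal)\n", object@nOrtho))
  cat(sprintf("  R2Y = %.4f, Q2 = %s\n", object@r2y,
              if (is.na(object@q2)) "not computed" else
                sprintf("%.4f", object@q2)))
  cat(sprintf("  features with VIP > 1: %d of %d\n",
              sum(object@vip > 1), length(object@vip)))
})
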
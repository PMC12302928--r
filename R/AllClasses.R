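#' Fitted principal component model
#'
#' Stores a PCA fit of a samples x features matrix: centering/scaling
#' vectors, sample scores, orthonormal feature loadings and the fraction of
#' total variance explained by each component.
#'
#' @slot center numeric, per-feature centering vector.
#' @slot scale numeric, per-feature scaling vector (length 0 if unscaled).
#' @slot scores matrix, samples x k component scores.
#' @slot loadings matrix, features x k orthonormal loadings.
#' @slot explainedVariance numeric, fraction of total variance per component,
#'   non-increasing, each in [0, 1], summing to at most 1.
#'
#' @seealso [fitPCA()]
#' @exportClass PcaModel
setClass("PcaModel",
  representation(
    center = "numeric",
    scale = "numeric",
    scores = "matrix",
    loadings = "matrix",
    explainedVariance = "numeric"
  )
)

setValidity("PcaModel", function(object) {
  msg <- character()
  k <- ncol(object@loadings)
  if (ncol(object@scores) != k)
    msg <- c(msg, "scores and loadings must have the same number of components")
  if (k > 0) {
    gram <- crossprod(object@loadings)
    if (max(abs(gram - diag(k))) > 1e-8)
      msg <- c(msg, "loadings columns must be orthonormal")
  }
  ev <- object@explainedVariance
  if (length(ev) != k)
    msg <- c(msg, "one explained-variance fraction per component required")
  if (length(ev) && (any(ev < -1e-12) || any(ev > 1 + 1e-12) ||
                     sum(ev) > 1 + 1e-8))
    msg <- c(msg, "explained-variance fractions must lie in [0,1], sum <= 1")
  if (length(ev) > 1 && any(diff(ev) > 1e-12))
    msg <- c(msg, "explained-variance fractions must be non-increasing")
  if (length(msg)) msg else TRUE
})

#' Fitted OPLS-DA model
#'
#' Orthogonal projections to latent structures discriminant analysis for a
#' two-class response: one predictive component plus `nOrtho` orthogonal
#' (class-uncorrelated) components. Holds the predictive scores/loadings/
#' weights, the orthogonal counterparts, the inner regression coefficient,
#' the explained class variance R2Y, the cross-validated Q2 (NA until
#' computed) and per-feature VIP scores normalized so that mean(VIP^2) = 1.
#'
#' @slot weights numeric, unit-norm predictive weight vector (one per feature).
#' @slot scores numeric, predictive score per sample.
#' @slot loadings numeric, predictive loading per feature.
#' @slot orthoWeights matrix, features x nOrtho orthogonal weights.
#' @slot orthoScores matrix, samples x nOrtho orthogonal scores.
#' @slot orthoLoadings matrix, features x nOrtho orthogonal loadings.
#' @slot coefficient numeric(1), inner regression of response on scores.
#' @slot r2y numeric(1), fraction of class-response variance explained.
#' @slot q2 numeric(1), cross-validated fraction (NA until computed).
#' @slot vip numeric, per-feature variable importance in projection.
#' @slot center,scale numeric, feature centering/scaling used for the fit.
#' @slot yCenter numeric(1), centering applied to the class indicator.
#' @slot classes character(2), class labels coded (-1, +1) in that order.
#' @slot nOrtho integer(1), number of orthogonal components.
#'
#' @seealso [fitOPLSDA()], [vipScores()], [crossValidatedQ2()]
#' @exportClass OplsModel
setClass("OplsModel",
  representation(
    weights = "numeric",
    scores = "numeric",
    loadings = "numeric",
    orthoWeights = "matrix",
    orthoScores = "matrix",
    orthoLoadings = "matrix",
    coefficient = "numeric",
    r2y = "numeric",
    q2 = "numeric",
    vip = "numeric",
    center = "numeric",
    scale = "numeric",
    yCenter = "numeric",
    classes = "character",
    nOrtho = "integer"
  )
)

setValidity("OplsModel", function(object) {
  msg <- character()
  if (object@r2y < -1e-8 || object@r2y > 1 + 1e-8)
    msg <- c(msg, "R2Y must lie in [0, 1]")
  if (object@nOrtho > 0) {
    orth <- crossprod(object@orthoScores, object@scores)
    if (max(abs(orth)) > 1e-6 * sqrt(sum(object@scores^2)))
      msg <- c(msg, "orthogonal scores must be orthogonal to predictive scores")
  }
  if (length(object@vip)) {
    if (abs(mean(object@vip^2) - 1) > 1e-8)
      msg <- c(msg, "mean of squared VIP scores must equal 1")
  }
  if (length(object@classes) != 2L)
    msg <- c(msg, "exactly two class labels required")
  if (length(msg)) msg else TRUE
})
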
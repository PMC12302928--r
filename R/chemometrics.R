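## Multivariate engine: PCA and Trygg-Wold OPLS-DA with VIP and
## cross-validated Q2. All fits work on log-transformed, autoscaled
## intensities; the transform is applied here, not stored in the tables.

# coerce a feature table or samples x features matrix to the analysis
# matrix; log-transform intensities coming from a feature table
.analysisMatrix <- function(x, log = TRUE) {
  if (methods::is(x, "SummarizedExperiment")) {
    m <- intensityMatrix(x)
    if (anyNA(m))
      stop("missing values present; impute before multivariate analysis")
    if (any(m <= 0))
      stop("non-positive intensities cannot be log-transformed")
    if (log) m <- base::log(m)
    return(m)
  }
  if (!is.matrix(x) || !is.numeric(x))
    stop("'x' must be a feature table or a numeric samples x features matrix")
  if (anyNA(x))
    stop("missing values present; impute before multivariate analysis")
  x
}

# center and (optionally) unit-variance scale; errors on constant features
.autoscale <- function(m, scale = TRUE) {
  ctr <- colMeans(m)
  mc <- sweep(m, 2L, ctr)
  scl <- numeric(0)
  if (scale) {
    scl <- apply(m, 2L, stats::sd)
    zero <- scl < .Machine$double.eps^0.5
    if (any(zero))
      stop("constant feature(s) under unit-variance scaling: ",
           paste(colnames(m)[zero], collapse = ", "))
    mc <- sweep(mc, 2L, scl, "/")
  }
  list(x = mc, center = ctr, scale = scl)
}

# flip the sign of a component so its largest-magnitude loading is positive
.fixSign <- function(loading) {
  i <- which.max(abs(loading))
  if (loading[i] < 0) -1 else 1
}

#' Principal component analysis
#'
#' Fits PCA by singular value decomposition of the centered (and by default
#' unit-variance scaled) samples x features matrix. When `x` is a feature
#' table its intensities are log-transformed first. Component signs follow
#' a fixed convention (largest-magnitude loading element positive) so
#' results are reproducible.
#'
#' @param x a feature table (see [featureTable()]) or a numeric samples x
#'   features matrix with no missing values.
#' @param k number of components, at most `min(n_samples - 1, n_features)`.
#' @param scale unit-variance scale each feature (default TRUE).
#' @param log log-transform intensities of a feature table (default TRUE;
#'   ignored for plain matrices).
#' @return A [PcaModel-class].
#' @export
fitPCA <- function(x, k = 2, scale = TRUE, log = TRUE) {
  m <- .analysisMatrix(x, log = log)
  kmax <- min(nrow(m) - 1L, ncol(m))
  .assertScalarNumber(k, "k", lower = 1, upper = kmax)
  k <- as.integer(k)
  sc <- .autoscale(m, scale = scale)
  sv <- svd(sc$x)
  signs <- vapply(seq_len(k), function(j) .fixSign(sv$v[, j]), numeric(1))
  scores <- sweep(sv$u[, seq_len(k), drop = FALSE] %*%
                    diag(sv$d[seq_len(k)], k), 2L, signs, "*")
  loadings <- sweep(sv$v[, seq_len(k), drop = FALSE], 2L, signs, "*")
  dimnames(scores) <- list(rownames(m), paste0("PC", seq_len(k)))
  dimnames(loadings) <- list(colnames(m), paste0("PC", seq_len(k)))
  total <- sum(sv$d^2)
  methods::new("PcaModel", center = sc$center, scale = sc$scale,
               scores = scores, loadings = loadings,
               explainedVariance = (sv$d[seq_len(k)]^2) / total)
}

# the Trygg-Wold core on an already centered/scaled X and centered y:
# the predictive weight is fixed from the original X; each orthogonal
# component removes the part of the X loading orthogonal to w
.oplsCore <- function(X, y, n_ortho) {
  w <- drop(crossprod(X, y))
  nw <- sqrt(sum(w^2))
  if (nw < .Machine$double.eps^0.5)
    stop("degenerate fit: X carries no covariance with the class indicator")
  w <- w / nw
  To <- matrix(0, nrow(X), n_ortho)
  Po <- matrix(0, ncol(X), n_ortho)
  Wo <- matrix(0, ncol(X), n_ortho)
  Xd <- X
  for (a in seq_len(n_ortho)) {
    t <- drop(Xd %*% w)
    p <- drop(crossprod(Xd, t)) / sum(t^2)
    wo <- p - sum(w * p) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < .Machine$double.eps^0.5)
      stop("no orthogonal variation left for component ", a)
    wo <- wo / nwo
    to <- drop(Xd %*% wo)
    po <- drop(crossprod(Xd, to)) / sum(to^2)
    Xd <- Xd - tcrossprod(to, po)
    To[, a] <- to; Po[, a] <- po; Wo[, a] <- wo
  }
  t <- drop(Xd %*% w)
  p <- drop(crossprod(Xd, t)) / sum(t^2)
  c <- sum(y * t) / sum(t^2)
  list(w = w, t = t, p = p, c = c, To = To, Po = Po, Wo = Wo)
}

# project new (already scaled) rows through the orthogonal filter and onto
# the predictive component
.oplsPredictScore <- function(core, xnew) {
  xnew <- matrix(xnew, ncol = length(core$w))
  if (ncol(core$To) > 0) {
    for (a in seq_len(ncol(core$To))) {
      to <- drop(xnew %*% core$Wo[, a])
      xnew <- xnew - tcrossprod(to, core$Po[, a])
    }
  }
  drop(xnew %*% core$w)
}

.codeClasses <- function(y) {
  y <- as.character(y)
  lv <- sort(unique(y))
  if (length(lv) != 2L)
    stop("exactly two classes required, got: ", paste(lv, collapse = ", "))
  counts <- table(y)
  if (any(counts < 2L))
    stop("each class needs at least 2 samples (class '",
         names(counts)[which.min(counts)], "' has ", min(counts), ")")
  list(coded = ifelse(y == lv[2], 1, -1), classes = lv)
}

#' Orthogonal PLS discriminant analysis (OPLS-DA)
#'
#' Fits a two-class OPLS-DA model by orthogonal projection to latent
#' structures: the predictive weight vector is the (normalized) covariance
#' of the scaled data with the centered class indicator; `nOrtho`
#' components of class-orthogonal variation are removed before the final
#' predictive component is extracted. With `nOrtho = 0` the model is
#' exactly one-component PLS1 on the class indicator. VIP scores are
#' computed over the predictive component and normalized so that
#' `mean(VIP^2) = 1`. Q2 is estimated by cross-validation (see
#' [crossValidatedQ2()]): leave-one-out for up to 12 samples, otherwise
#' seeded stratified 7-fold.
#'
#' @param x feature table or samples x features matrix (no missing values).
#' @param y two-level class labels, one per sample.
#' @param nOrtho number of orthogonal components (default 1); must be less
#'   than the rank of the centered data.
#' @param scale,log as in [fitPCA()].
#' @param cv compute cross-validated Q2 (default TRUE).
#' @param cvSeed seed for the stratified fold assignment when n > 12.
#' @return An [OplsModel-class].
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(9 * 30), 9, 30)
#' y <- rep(c("A", "B"), c(4, 5))
#' x[, 1] <- x[, 1] + 3 * (y == "B")
#' m <- fitOPLSDA(x, y)
#' r2y(m); q2(m)
#' @export
fitOPLSDA <- function(x, y, nOrtho = 1, scale = TRUE, log = TRUE,
                      cv = TRUE, cvSeed = 1L) {
  m <- .analysisMatrix(x, log = log)
  cls <- .codeClasses(y)
  if (length(cls$coded) != nrow(m))
    stop("'y' must have one label per sample")
  nOrtho <- as.integer(nOrtho)
  rk <- qr(scale(m, scale = FALSE))$rank
  if (nOrtho < 0 || nOrtho >= rk)
    stop("nOrtho must lie in [0, rank); rank of the centered data is ", rk)
  sc <- .autoscale(m, scale = scale)
  yc <- cls$coded - mean(cls$coded)
  core <- .oplsCore(sc$x, yc, nOrtho)
  # sign convention: largest-magnitude predictive loading positive
  s <- .fixSign(core$p)
  core$w <- s * core$w; core$t <- s * core$t
  core$p <- s * core$p; core$c <- s * core$c
  if (nOrtho > 0) {
    so <- vapply(seq_len(nOrtho), function(a) .fixSign(core$Po[, a]),
                 numeric(1))
    core$To <- sweep(core$To, 2L, so, "*")
    core$Po <- sweep(core$Po, 2L, so, "*")
    core$Wo <- sweep(core$Wo, 2L, so, "*")
  }
  ssy <- sum(yc^2)
  if (ssy < .Machine$double.eps)
    stop("class indicator has zero variance")
  r2 <- 1 - sum((yc - core$c * core$t)^2) / ssy
  vip <- .vipFromCore(core, yc)
  names(vip) <- colnames(m)
  q2v <- NA_real_
  if (cv)
    q2v <- crossValidatedQ2(m, y, nOrtho = nOrtho, scale = scale,
                            log = FALSE, seed = cvSeed)
  methods::new("OplsModel",
               weights = stats::setNames(core$w, colnames(m)),
               scores = stats::setNames(core$t, rownames(m)),
               loadings = stats::setNames(core$p, colnames(m)),
               orthoWeights = core$Wo, orthoScores = core$To,
               orthoLoadings = core$Po,
               coefficient = core$c, r2y = min(max(r2, 0), 1), q2 = q2v,
               vip = vip, center = sc$center, scale = sc$scale,
               yCenter = mean(cls$coded), classes = cls$classes,
               nOrtho = nOrtho)
}

# VIP over predictive components: with one predictive component and unit
# w, vip_j = sqrt(F) * |w_j|, which forces mean(vip^2) = 1
.vipFromCore <- function(core, yc) {
  ssy_a <- core$c^2 * sum(core$t^2)
  if (ssy_a <= 0)
    stop("zero explained class variance; VIP undefined")
  F <- length(core$w)
  sqrt(F * ssy_a * (core$w / sqrt(sum(core$w^2)))^2 / ssy_a)
}

#' Cross-validated Q2 for OPLS-DA
#'
#' Computes `Q2 = 1 - PRESS / SSY`: each fold's samples are predicted from
#' a model refit on the remaining samples (centering, scaling, orthogonal
#' filtering and the predictive regression all re-estimated on the
#' training fold). Leave-one-out is used when `folds` is `NULL` and
#' `n <= 12`; otherwise seeded stratified 7-fold assignment. Every
#' training fold must retain both classes.
#'
#' @param x feature table or samples x features matrix.
#' @param y two-level class labels.
#' @param nOrtho orthogonal components, as in [fitOPLSDA()].
#' @param folds number of folds, or `NULL` for the automatic rule; `folds
#'   = n` is leave-one-out.
#' @param scale,log as in [fitPCA()].
#' @param seed seed for the stratified fold assignment (ignored for LOO).
#' @return The Q2 statistic (can be negative for models that predict worse
#'   than the class mean).
#' @export
crossValidatedQ2 <- function(x, y, nOrtho = 1, folds = NULL, scale = TRUE,
                             log = TRUE, seed = 1L) {
  m <- .analysisMatrix(x, log = log)
  cls <- .codeClasses(y)
  n <- nrow(m)
  if (is.null(folds)) folds <- if (n <= 12L) n else 7L
  folds <- as.integer(folds)
  if (folds < 2L || folds > n)
    stop("'folds' must lie in [2, n_samples]")
  if (folds == n) {
    assignment <- seq_len(n)
  } else {
    assignment <- integer(n)
    .withSeed(seed, for (lv in unique(cls$classes)) {
      idx <- sample(which(as.character(y) == lv))
      assignment[idx] <- rep_len(seq_len(folds), length(idx))
    })
  }
  yc_full <- cls$coded - mean(cls$coded)
  press <- 0
  for (f in unique(assignment)) {
    test <- assignment == f
    ytr <- cls$coded[!test]
    if (length(unique(ytr)) < 2L)
      stop("fold ", f, " leaves a class empty in the training set")
    sc <- .autoscale(m[!test, , drop = FALSE], scale = scale)
    core <- .oplsCore(sc$x, ytr - mean(ytr), nOrtho)
    xte <- sweep(m[test, , drop = FALSE], 2L, sc$center)
    if (scale) xte <- sweep(xte, 2L, sc$scale, "/")
    pred <- core$c * .oplsPredictScore(core, xte) + mean(ytr)
    press <- press + sum((cls$coded[test] - pred)^2)
  }
  1 - press / sum(yc_full^2)
}
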
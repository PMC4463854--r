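## Linear discriminant analysis on latent scores, the composed PLS-LDA
## classifier, and JSON model serialization.

#' Fit an LDA model on latent scores
#'
#' Gaussian classes with a common covariance: class means are the per-class
#' score means; the covariance is the pooled within-class estimate. When the
#' pooled covariance is ill-conditioned (condition number above `condMax`) a
#' ridge floor of `1e-8 * trace / K` is added to the diagonal; if it remains
#' singular the fit errors.
#'
#' @param T numeric `N x K` latent score matrix.
#' @param y 0/1 class vector; both classes need at least 2 observations.
#' @param priors `"equal"` (default) or `"empirical"` class priors.
#' @param condMax condition-number threshold triggering the ridge floor.
#' @return An [LdaModel-class].
#' @export
fitLda <- function(T, y, priors = c("equal", "empirical"), condMax = 1e8) {
  priors <- match.arg(priors)
  T <- as.matrix(T); y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be coded 0/1")
  n0 <- sum(y == 0); n1 <- sum(y == 1)
  if (n0 < 2 || n1 < 2) stop("each class needs at least 2 observations")
  K <- ncol(T)
  mu <- rbind(colMeans(T[y == 0, , drop = FALSE]),
              colMeans(T[y == 1, , drop = FALSE]))
  C0 <- T[y == 0, , drop = FALSE] - matrix(mu[1, ], n0, K, byrow = TRUE)
  C1 <- T[y == 1, , drop = FALSE] - matrix(mu[2, ], n1, K, byrow = TRUE)
  S <- (crossprod(C0) + crossprod(C1)) / (n0 + n1 - 2)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / max(min(ev), .Machine$double.xmin) > condMax)
    S <- S + diag(1e-8 * sum(diag(S)) / K, K)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("pooled covariance is singular even after the ridge floor")
  pr <- if (priors == "equal") c(0.5, 0.5) else c(n0, n1) / (n0 + n1)
  new("LdaModel", means = mu, pooledCov = S, priors = pr)
}

## Mahalanobis distances to both class means; rows = observations
.ldaDistances <- function(lda, T) {
  T <- as.matrix(T)
  Sinv <- solve(lda@pooledCov)
  d <- vapply(1:2, function(g) {
    C <- sweep(T, 2, lda@means[g, ])
    rowSums((C %*% Sinv) * C)
  }, numeric(nrow(T)))
  matrix(d, nrow = nrow(T))
}

#' Fit the PLS-LDA classifier
#'
#' Composition of the pipeline's two stages: the latent component count K is
#' chosen by leave-one-out PRESS, a PLS model with K components is fitted,
#' and an LDA model with pooled covariance is fitted on the training latent
#' scores. Class labels are mapped to 0/1 in the order given by
#' `classLabels` (or sorted unique labels).
#'
#' Note on the decision rule: the discriminant assigns an observation to the
#' class with the *smaller* Mahalanobis distance to its mean (standard LDA);
#' see [predict,PlsLdaModel-method].
#'
#' @param X numeric `N x d` feature matrix.
#' @param y class labels: 0/1, or any two labels (mapped via `classLabels`).
#' @param aMax largest component count considered by PRESS (default
#'   `min(8, d, N-2)`).
#' @param autoscale scale columns to unit training variance before PLS
#'   (default FALSE: mean-centering only).
#' @param priors passed to [fitLda()].
#' @param classLabels length-2 character giving the labels mapped to 0 and 1.
#' @return A [PlsLdaModel-class].
#' @export
fitPlsLda <- function(X, y, aMax = NULL, autoscale = FALSE,
                      priors = "equal", classLabels = NULL) {
  X <- as.matrix(X)
  if (is.null(classLabels)) {
    classLabels <- if (all(y %in% c(0, 1))) c("0", "1") else sort(unique(as.character(y)))
  }
  if (all(y %in% c(0, 1)) && is.numeric(y)) y01 <- as.numeric(y)
  else y01 <- as.numeric(match(as.character(y), classLabels) - 1)
  if (any(is.na(y01))) stop("labels outside classLabels")
  if (is.null(aMax)) aMax <- max(1, min(8, ncol(X), nrow(X) - 2))
  scale_ <- rep(1, ncol(X))
  if (autoscale) {
    scale_ <- apply(X, 2, stats::sd)
    scale_[scale_ == 0] <- 1
    X <- sweep(X, 2, scale_, "/")
  }
  K <- selectComponentsPress(X, y01, aMax)$K
  pls <- suppressWarnings(fitPls(X, y01, K))
  K <- pls@A  # may have truncated at numerical rank
  lda <- fitLda(plsScores(pls, X), y01, priors = priors)
  new("PlsLdaModel", pls = pls, lda = lda, K = as.integer(K),
      classLabels = classLabels,
      scale = if (autoscale) scale_ else numeric(0))
}

#' Predict classes with a PLS-LDA model
#'
#' New observations are centered by the training means, projected to latent
#' scores, and assigned to the class with the smaller Mahalanobis distance
#' \eqn{(T - \hat\mu_g) \hat\Sigma^{-1} (T - \hat\mu_g)^\top} (minus twice
#' the log prior when priors are unequal). The continuous discriminant
#' score is the signed difference D(class 0) - D(class 1): positive favors
#' class 1; exact ties resolve to class 0.
#'
#' @param object a [PlsLdaModel-class].
#' @param newdata numeric matrix (or single vector) with the training
#'   feature dimensionality.
#' @return A data.frame with columns `class` (0/1), `label`, and `score`.
#' @importFrom stats predict
#' @export
setMethod("predict", "PlsLdaModel", function(object, newdata) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (length(object@scale)) newdata <- sweep(newdata, 2, object@scale, "/")
  T <- plsScores(object@pls, newdata)
  D <- .ldaDistances(object@lda, T)
  D <- sweep(D, 2, 2 * log(object@lda@priors), "-")
  score <- D[, 1] - D[, 2]
  cls <- as.integer(score > 0)
  data.frame(class = cls, label = object@classLabels[cls + 1],
             score = score, row.names = rownames(newdata))
})

#' Serialize a PLS-LDA model to JSON
#'
#' Writes every parameter needed for exact reload: centering constants,
#' weights, loadings, projection, training scores, inner coefficients, LDA
#' means/covariance/priors, K, class labels and the autoscale factors.
#'
#' @param model a [PlsLdaModel-class].
#' @param path output file; if NULL the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
writePlsLdaModel <- function(model, path = NULL) {
  obj <- list(
    xMeans = model@pls@xMeans, yMean = model@pls@yMean,
    weights = model@pls@weights, loadings = model@pls@loadings,
    yLoadings = model@pls@yLoadings, innerCoef = model@pls@innerCoef,
    scores = model@pls@scores, projection = model@pls@projection,
    A = model@pls@A, ldaMeans = model@lda@means,
    pooledCov = model@lda@pooledCov, priors = model@lda@priors,
    K = model@K, classLabels = model@classLabels,
    autoscale = if (length(model@scale)) model@scale else NULL)
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE, null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' Reload a PLS-LDA model from JSON
#'
#' @param path file written by [writePlsLdaModel()] (or a JSON string).
#' @return A [PlsLdaModel-class].
#' @export
readPlsLdaModel <- function(path) {
  obj <- jsonlite::fromJSON(path)
  asm <- function(x) if (is.null(dim(x))) matrix(x, ncol = 1) else as.matrix(x)
  pls <- new("PlsModel", xMeans = as.numeric(obj$xMeans),
             yMean = as.numeric(obj$yMean), weights = asm(obj$weights),
             loadings = asm(obj$loadings), yLoadings = as.numeric(obj$yLoadings),
             innerCoef = as.numeric(obj$innerCoef), scores = asm(obj$scores),
             projection = asm(obj$projection), A = as.integer(obj$A))
  lda <- new("LdaModel", means = asm(obj$ldaMeans),
             pooledCov = asm(obj$pooledCov), priors = as.numeric(obj$priors))
  new("PlsLdaModel", pls = pls, lda = lda, K = as.integer(obj$K),
      classLabels = as.character(obj$classLabels),
      scale = if (is.null(obj$autoscale)) numeric(0) else as.numeric(obj$autoscale))
}
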
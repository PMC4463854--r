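## Partial least squares (single 0/1 response, NIPALS extraction) and
## PRESS-based selection of the latent component count.

## Fast internal PLS1 fit on a plain matrix/vector; returns lists only.
## With a single response, each NIPALS component has the closed form
## w = X'y / ||X'y||, so extraction is purely sequential deflation.
.plsFit <- function(X, y, A, tol = 1e-12) {
  n <- nrow(X); d <- ncol(X)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm); yc <- y - ym
  Wm <- matrix(0, d, A); Pm <- matrix(0, d, A)
  Tm <- matrix(0, n, A); q <- numeric(A)
  x0 <- sum(Xc^2)
  a <- 0
  while (a < A) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w^2))
    if (nw < tol * max(1, sqrt(x0))) break
    w <- w / nw
    tt <- Xc %*% w
    t2 <- sum(tt^2)
    if (t2 < tol * max(1, x0)) break
    p <- crossprod(Xc, tt) / t2
    qa <- sum(yc * tt) / t2
    a <- a + 1
    Wm[, a] <- w; Pm[, a] <- p; Tm[, a] <- tt; q[a] <- qa
    Xc <- Xc - tcrossprod(tt, p)
    yc <- yc - qa * tt
  }
  if (a == 0) stop("no PLS component could be extracted (X'y is null)")
  Wm <- Wm[, seq_len(a), drop = FALSE]; Pm <- Pm[, seq_len(a), drop = FALSE]
  Tm <- Tm[, seq_len(a), drop = FALSE]; q <- q[seq_len(a)]
  ## projection mapping centered x to scores: R = W (P'W)^-1
  R <- Wm %*% solve(crossprod(Pm, Wm))
  list(xMeans = xm, yMean = ym, W = Wm, P = Pm, q = q, T = Tm, R = R,
       A = a, requested = A)
}

## latent scores of new observations (all components at once)
.plsScores <- function(fit, Xnew) {
  sweep(as.matrix(Xnew), 2, fit$xMeans) %*% fit$R
}

## cumulative regression predictions at every component count 1..A
.plsPredictCum <- function(fit, Xnew) {
  S <- .plsScores(fit, Xnew)
  sw <- sweep(S, 2, fit$q, "*")
  fit$yMean + t(apply(sw, 1, cumsum))
}

#' Fit a partial least squares model
#'
#' Sequential NIPALS extraction of `A` latent components from mean-centered
#' predictors and a 0/1 class response, deflating X after each component.
#' Each weight vector maximizes covariance between the X score and the
#' current response residual; scores of distinct components are orthogonal.
#' If the numerical rank of X is exhausted before `A` components, the model
#' is truncated with a warning.
#'
#' @param X numeric `N x d` predictor matrix.
#' @param y response coded 0/1 (both classes present).
#' @param A number of latent components, `1 <= A <= min(d, N-1)`.
#' @return A [PlsModel-class].
#' @export
fitPls <- function(X, y, A) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); d <- ncol(X)
  if (n < 3) stop("at least 3 observations are required")
  if (!all(y %in% c(0, 1))) stop("y must be coded 0/1")
  if (length(unique(y)) < 2) stop("both classes must be present in y")
  if (A < 1 || A > min(d, n - 1))
    stop(sprintf("A must lie in [1, %d]", min(d, n - 1)))
  fit <- .plsFit(X, y, A)
  if (fit$A < fit$requested)
    warning(sprintf("X rank exhausted: model truncated at %d of %d components",
                    fit$A, fit$requested))
  new("PlsModel", xMeans = fit$xMeans, yMean = fit$yMean, weights = fit$W,
      loadings = fit$P, yLoadings = fit$q, innerCoef = fit$q,
      scores = fit$T, projection = fit$R, A = as.integer(fit$A))
}

#' Latent scores of new observations
#'
#' Projects (training-mean-centered) observations onto the latent components
#' of a fitted PLS model.
#'
#' @param model a [PlsModel-class].
#' @param X numeric matrix (or vector) with the training dimensionality.
#' @return `n x A` score matrix.
#' @export
plsScores <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != nrow(model@weights))
    stop(sprintf("x has %d features, model expects %d",
                 ncol(X), nrow(model@weights)))
  sweep(as.matrix(X), 2, model@xMeans) %*% model@projection
}

#' PLS regression predictions
#'
#' Fitted response values of the PLS regression at the model's component
#' count (continuous; not yet a class decision).
#'
#' @inheritParams plsScores
#' @return Numeric vector of predictions.
#' @export
plsPredict <- function(model, X) {
  as.numeric(model@yMean + plsScores(model, X) %*% model@yLoadings)
}

#' Select the PLS component count by PRESS
#'
#' Leave-one-out prediction residual sum of squares of the PLS regression:
#' for every held-out observation the model is refitted from scratch on the
#' remaining data with up to `aMax` components and the held-out response is
#' predicted at every component count. Returns the count minimizing PRESS,
#' taking the smallest count on ties.
#'
#' @param X numeric `N x d` predictor matrix.
#' @param y 0/1 response.
#' @param aMax largest component count to consider.
#' @return List with `K` (selected count) and `press` (PRESS at 1..aMax).
#' @export
selectComponentsPress <- function(X, y, aMax) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  aMax <- min(aMax, ncol(X), n - 2)
  if (aMax < 1) stop("too few observations/features for PRESS selection")
  sqerr <- matrix(NA_real_, n, aMax)
  for (i in seq_len(n)) {
    yi <- y[-i]
    if (length(unique(yi)) < 2) {
      ## fold degenerates to one class: predict its mean at every count
      sqerr[i, ] <- (y[i] - mean(yi))^2
      next
    }
    fit <- .plsFit(X[-i, , drop = FALSE], yi, aMax)
    pred <- .plsPredictCum(fit, X[i, , drop = FALSE])[1, ]
    if (fit$A < aMax) pred <- c(pred, rep(pred[fit$A], aMax - fit$A))
    sqerr[i, ] <- (y[i] - pred)^2
  }
  press <- colSums(sqerr)
  list(K = which.min(press), press = press)
}
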
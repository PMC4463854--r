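## Simple (single-feature) logistic regression screen with Wald inference,
## fitted by iteratively reweighted least squares.

#' Logistic regression by IRLS
#'
#' Maximum-likelihood logistic regression via iteratively reweighted least
#' squares, with Wald standard errors from the observed information. Fits
#' diverging toward perfect separation (unbounded coefficients) are flagged
#' rather than reported as silent huge numbers.
#'
#' @param X numeric design matrix (an intercept column is prepended).
#' @param y 0/1 outcome vector.
#' @param maxit,tol IRLS iteration cap and convergence tolerance on the
#'   coefficient step.
#' @return List with `beta`, `se`, `z`, `p` (Wald, normal approximation),
#'   `fitted` probabilities, `converged`, and `separated`.
#' @export
logisticFit <- function(X, y, maxit = 100L, tol = 1e-10) {
  X <- cbind(`(Intercept)` = 1, as.matrix(X))
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)))
  beta <- numeric(ncol(X))
  converged <- FALSE; separated <- FALSE
  for (it in seq_len(maxit)) {
    eta <- as.numeric(X %*% beta)
    if (max(abs(eta)) > 30) { separated <- TRUE; break }
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    XtWX <- crossprod(X, X * w)
    step <- tryCatch(solve(XtWX, crossprod(X, y - p)),
                     error = function(e) NULL)
    if (is.null(step)) { separated <- TRUE; break }
    beta <- beta + as.numeric(step)
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  eta <- as.numeric(X %*% beta)
  p <- stats::plogis(eta)
  if (separated) {
    se <- rep(NA_real_, length(beta))
  } else {
    w <- p * (1 - p)
    se <- sqrt(diag(solve(crossprod(X, X * w))))
  }
  z <- beta / se
  list(beta = beta, se = se, z = z,
       p = 2 * stats::pnorm(-abs(z)), fitted = p,
       converged = converged, separated = separated)
}

#' Per-feature simple logistic regression screen
#'
#' Fits `outcome ~ intercept + feature` separately for every feature of the
#' table (no covariates), reporting the feature's coefficient, Wald standard
#' error and p-value, and the AU-ROC of the fitted probabilities. The
#' outcome is 1 for the more impaired diagnosis. Perfectly separating
#' features are flagged with an infinite-beta marker (signed Inf, NA
#' standard error and p).
#'
#' @param table a [FeatureTable-class] restricted to two diagnoses.
#' @return data.frame with one row per feature: `feature`, `region`,
#'   `modality`, `beta`, `se`, `p`, `auc`, `separated`.
#' @export
logisticScreen <- function(table) {
  dx <- diagnosis(table)
  if (length(unique(dx)) != 2) stop("exactly two diagnostic groups required")
  posClass <- positiveClassOf(dx)
  y <- as.numeric(dx == posClass)
  if (sum(y) < 2 || sum(1 - y) < 2) stop("both classes need >= 2 subjects")
  X <- featureMatrix(table)
  rd <- SummarizedExperiment::rowData(table)
  rows <- lapply(seq_len(ncol(X)), function(j) {
    fit <- logisticFit(X[, j, drop = FALSE], y)
    beta <- fit$beta[2]; se <- fit$se[2]; p <- fit$p[2]
    if (fit$separated) {
      beta <- sign(mean(X[y == 1, j]) - mean(X[y == 0, j])) * Inf
      se <- NA_real_; p <- NA_real_
    }
    auc <- rocFromScores(fit$fitted, dx, posClass)$auc
    data.frame(feature = colnames(X)[j],
               region = as.character(rd$region[j]),
               modality = as.character(rd$modality[j]),
               beta = beta, se = se, p = p, auc = auc,
               separated = fit$separated)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
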
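## Synthetic feature cohorts: multivariate Gaussian subject draws with
## controlled per-feature group mean shifts and correlation structure.

#' Cohort specification
#'
#' Parameters of a synthetic feature cohort: group sizes, the feature
#' lexicon (default the 24 selected multimodal feature names), per-feature
#' group mean shifts in within-group SD units, and the common correlation
#' structure. Defaults mirror the study conditions: NC and AD groups of 85
#' and 71 subjects, unit feature variances with exchangeable correlation
#' 0.3, and the patient group shifted -1.5 SD on the 12 FDG features
#' (regional hypometabolism; negative shifts for the impaired group match
#' the direction of the regional logistic coefficients).
#'
#' @param groups named integer vector of group sizes; names are diagnoses
#'   (default `c(NC = 85, AD = 71)`).
#' @param features character vector of feature names, formatted
#'   `"<modality>: <region>"` (default [smfFeatureNames()]).
#' @param shifts named list: per non-reference group, a numeric vector of
#'   mean shifts (SD units) of length `length(features)`. The first group is
#'   the reference at 0. Default: AD at -1.5 on the FDG features.
#' @param correlation exchangeable inter-feature correlation (default 0.3),
#'   or a full correlation/covariance matrix.
#' @param seed integer seed.
#' @return A list of validated parameters (class `cohortSpec`).
#' @export
cohortSpec <- function(groups = c(NC = 85L, AD = 71L),
                       features = smfFeatureNames(),
                       shifts = NULL, correlation = 0.3, seed = 1L) {
  if (is.null(names(groups))) stop("groups must be a named vector of sizes")
  p <- length(features)
  if (is.null(shifts)) {
    shifts <- stats::setNames(
      lapply(names(groups)[-1], function(g)
        ifelse(.featureModality(features) == "FDG", -1.5, 0)),
      names(groups)[-1])
  }
  for (g in names(shifts))
    if (length(shifts[[g]]) != p)
      stop(sprintf("shift vector for group '%s' must have length %d", g, p))
  Sigma <- if (is.matrix(correlation)) correlation
           else matrix(correlation, p, p) + diag(1 - correlation, p)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) stop("covariance is not positive definite")
  structure(list(groups = groups, features = features, shifts = shifts,
                 Sigma = Sigma, seed = as.integer(seed)),
            class = "cohortSpec")
}

#' Generate a synthetic feature cohort
#'
#' Draws each group from a multivariate Gaussian with the specified mean
#' shifts and common covariance, attaches diagnosis labels, and returns the
#' assembled [FeatureTable-class] together with the generating truth.
#' Deterministic for a fixed seed.
#'
#' @param spec a [cohortSpec()].
#' @return List with `table` (a [FeatureTable-class]) and `truth`
#'   (the per-group mean shifts and the covariance).
#' @export
generateCohort <- function(spec = cohortSpec()) {
  stopifnot(inherits(spec, "cohortSpec"))
  set.seed(spec$seed)
  p <- length(spec$features)
  blocks <- lapply(names(spec$groups), function(g) {
    mu <- if (g %in% names(spec$shifts)) spec$shifts[[g]] else rep(0, p)
    MASS::mvrnorm(spec$groups[[g]], mu = mu, Sigma = spec$Sigma)
  })
  vals <- do.call(rbind, blocks)
  colnames(vals) <- spec$features
  rownames(vals) <- sprintf("subj%03d", seq_len(nrow(vals)))
  dxg <- rep(names(spec$groups), spec$groups)
  table <- FeatureTable(vals, diagnosis = dxg,
                        modality = .featureModality(spec$features),
                        source = ifelse(.featureRegion(spec$features) == "hippocampus",
                                        "volume", "surface"),
                        region = .featureRegion(spec$features))
  list(table = table,
       truth = list(shifts = spec$shifts, Sigma = spec$Sigma,
                    groups = spec$groups))
}
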
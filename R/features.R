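## Feature extraction: hippocampal and volumetric regional features,
## multimodal feature-table assembly, and data-driven region selection.

#' Hippocampal volume and corrected uptake
#'
#' The two hippocampal features: segmented hippocampal volume normalized by
#' the intracranial volume (dimensionless ratio), and mean partial-volume-
#' corrected uptake inside the hippocampus mask, obtained by dividing the
#' DVR image by the PSF-smoothed weighted-PVE map (voxels whose smoothed
#' wPVE falls below `epsilon` are excluded from the mean).
#'
#' @param dvr normalized uptake [VolumeImage-class].
#' @param tissues [TissueFractions-class] co-registered with `dvr`.
#' @param hipMask hippocampus [BinaryMask-class].
#' @param icvMask intracranial [BinaryMask-class].
#' @param petFwhm wPVE smoothing FWHM in mm (default 6).
#' @param epsilon wPVE division floor (default 0.05).
#' @return List with `volume` (hippocampus/ICV volume ratio) and `uptake`
#'   (mean corrected uptake).
#' @export
hippocampalFeatures <- function(dvr, tissues, hipMask, icvMask,
                                petFwhm = 6, epsilon = 0.05) {
  stopifnot(is(hipMask, "BinaryMask"), is(icvMask, "BinaryMask"))
  if (sum(hipMask@data) == 0) stop("hippocampus mask is empty")
  if (sum(icvMask@data) == 0) stop("intracranial mask is empty")
  hs <- maskedStats(dvr, hipMask)
  is_ <- maskedStats(dvr, icvMask)
  wpve <- gaussianSmooth(weightedPVE(tissues), petFwhm)
  inmask <- hipMask@data > 0
  den <- wpve@data[inmask]
  ok <- den >= epsilon
  if (!any(ok)) stop("smoothed wPVE below floor at every hippocampal voxel")
  list(volume = hs$volume / is_$volume,
       uptake = mean(dvr@data[inmask][ok] / den[ok]))
}

#' Volume-based regional features
#'
#' Per labeled region: GM volume (sum of GM fraction times voxel volume,
#' normalized by the intracranial volume) and mean partial-volume-corrected
#' uptake (DVR divided by the PSF-smoothed wPVE, floor `epsilon`). Regions
#' with no voxels are omitted with a message.
#'
#' @param dvr normalized uptake [VolumeImage-class].
#' @param tissues [TissueFractions-class].
#' @param labelVol [VolumeImage-class] of integer region ids (0 = none).
#' @param lexicon named character vector mapping id (string) to region name.
#' @param icvMask intracranial [BinaryMask-class].
#' @inheritParams hippocampalFeatures
#' @return List of two named numeric vectors, `gmVolume` (ICV-normalized)
#'   and `uptake`, over the populated regions.
#' @export
volumetricFeatures <- function(dvr, tissues, labelVol, lexicon, icvMask,
                               petFwhm = 6, epsilon = 0.05) {
  .sameGrid(dvr, labelVol, "dvr and label volume")
  ids <- as.integer(round(labelVol@data))
  wpve <- gaussianSmooth(weightedPVE(tissues), petFwhm)
  icv <- sum(icvMask@data) * voxelVolume(icvMask)
  vv <- voxelVolume(dvr)
  corrected <- ifelse(wpve@data >= epsilon, dvr@data / wpve@data, NA_real_)
  keep <- ids != 0L
  gmsum <- rowsum(as.numeric(tissues@gm@data)[keep], ids[keep])
  upt <- rowsum(as.numeric(corrected)[keep], ids[keep], na.rm = TRUE)
  uptn <- rowsum(as.numeric(!is.na(corrected))[keep], ids[keep])
  rn <- rownames(gmsum)
  gmVolume <- stats::setNames(as.numeric(gmsum) * vv / icv, lexicon[rn])
  uptake <- stats::setNames(as.numeric(upt) / pmax(as.numeric(uptn), 1), lexicon[rn])
  empty <- setdiff(names(lexicon), rn)
  if (length(empty))
    message(sprintf("regions with no voxels omitted: %s",
                    paste(lexicon[empty], collapse = ", ")))
  list(gmVolume = gmVolume, uptake = uptake)
}

## pull one named regional value, with a precise error
.needRegion <- function(vec, region, subject, what) {
  if (is.null(vec) || !region %in% names(vec) || is.na(vec[region]))
    stop(sprintf("subject '%s' is missing %s for region '%s'",
                 subject, what, region))
  unname(vec[region])
}

#' Assemble a multimodal feature table
#'
#' Builds the subjects-by-features [FeatureTable-class] for one of the
#' feature schemes:
#' \describe{
#'   \item{SMF}{24 selected multimodal features: MRI (thickness; hippocampal
#'     volume) and FDG (csFDG uptake; corrected hippocampal uptake) over the
#'     12 predefined regions.}
#'   \item{SSF-MRI / SSF-FDG}{the 12 single-modality columns of SMF.}
#'   \item{all}{80 whole-brain features: both modalities over all 39
#'     cortical regions plus the hippocampus.}
#'   \item{volume-based}{24 features over the predefined regions using
#'     volumetric GM volumes and masked corrected uptake instead of the
#'     surface maps.}
#' }
#'
#' @param subjects named list, one entry per subject, each a list with named
#'   regional vectors `thickness` and `csfdg` (cortical regions), scalars
#'   `hipVolume` and `hipUptake`, and — for the volume-based scheme —
#'   `gmVolume` and `volUptake` regional vectors.
#' @param diagnosis character vector of per-subject labels (NC/MCI/AD),
#'   aligned with `subjects`.
#' @param scheme one of `"SMF"`, `"SSF-MRI"`, `"SSF-FDG"`, `"all"`,
#'   `"volume-based"`.
#' @param regions region set for the SMF/SSF/volume-based schemes (default
#'   the 12 predefined regions; pass a data-driven set to reproduce the
#'   comparison configuration).
#' @return A [FeatureTable-class].
#' @export
assembleFeatures <- function(subjects, diagnosis,
                             scheme = c("SMF", "SSF-MRI", "SSF-FDG", "all",
                                        "volume-based"),
                             regions = predefinedRegions()) {
  scheme <- match.arg(scheme)
  if (length(diagnosis) != length(subjects))
    stop("diagnosis length must match the number of subjects")
  if (scheme == "all") regions <- allRegions()
  mods <- switch(scheme, `SSF-MRI` = "MRI", `SSF-FDG` = "FDG", c("MRI", "FDG"))
  src <- if (scheme == "volume-based") "volume" else "surface"
  cols <- expand.grid(region = regions, modality = mods,
                      stringsAsFactors = FALSE)
  subjnames <- names(subjects)
  if (is.null(subjnames)) subjnames <- sprintf("subj%03d", seq_along(subjects))
  vals <- matrix(NA_real_, length(subjects), nrow(cols),
                 dimnames = list(subjnames,
                                 .featureName(cols$modality, cols$region)))
  for (s in seq_along(subjects)) {
    sub <- subjects[[s]]; id <- subjnames[s]
    for (c in seq_len(nrow(cols))) {
      rg <- cols$region[c]; md <- cols$modality[c]
      vals[s, c] <- if (rg == "hippocampus") {
        if (md == "MRI") .needRegion(c(hippocampus = sub$hipVolume),
                                     "hippocampus", id, "hippocampal volume")
        else .needRegion(c(hippocampus = sub$hipUptake),
                         "hippocampus", id, "hippocampal uptake")
      } else if (scheme == "volume-based") {
        if (md == "MRI") .needRegion(sub$gmVolume, rg, id, "GM volume")
        else .needRegion(sub$volUptake, rg, id, "volumetric uptake")
      } else {
        if (md == "MRI") .needRegion(sub$thickness, rg, id, "thickness")
        else .needRegion(sub$csfdg, rg, id, "csFDG uptake")
      }
    }
  }
  srcvec <- ifelse(cols$region == "hippocampus", "volume", src)
  FeatureTable(vals, diagnosis = diagnosis, modality = cols$modality,
               source = srcvec, region = cols$region)
}

#' Data-driven region selection by two-sample t statistics
#'
#' Ranks regions by the absolute two-sample t statistic (pooled variance by
#' default; `welch = TRUE` for unequal variances) between two diagnostic
#' groups and returns the top `k` region names. A region carrying several
#' features (one per modality) is scored by the largest |t| across its
#' features. Ties break deterministically by region name.
#'
#' @param table a [FeatureTable-class].
#' @param groupA,groupB diagnosis labels of the two groups to contrast.
#' @param k number of regions to select (default 12).
#' @param welch use Welch's t instead of pooled-variance t.
#' @return Character vector of `k` region names, strongest first.
#' @export
selectDataDriven <- function(table, groupA, groupB, k = 12, welch = FALSE) {
  dx <- diagnosis(table)
  X <- featureMatrix(table)
  ia <- dx == groupA; ib <- dx == groupB
  if (sum(ia) < 2 || sum(ib) < 2)
    stop("both groups need at least 2 subjects")
  regions <- as.character(SummarizedExperiment::rowData(table)$region)
  uregions <- sort(unique(regions))
  if (k > length(uregions))
    stop(sprintf("k = %d exceeds the %d available regions", k, length(uregions)))
  tstat <- vapply(seq_len(ncol(X)), function(j) {
    xa <- X[ia, j]; xb <- X[ib, j]
    na <- length(xa); nb <- length(xb)
    if (welch) {
      (mean(xa) - mean(xb)) / sqrt(stats::var(xa) / na + stats::var(xb) / nb)
    } else {
      sp2 <- ((na - 1) * stats::var(xa) + (nb - 1) * stats::var(xb)) / (na + nb - 2)
      (mean(xa) - mean(xb)) / sqrt(sp2 * (1 / na + 1 / nb))
    }
  }, numeric(1))
  score <- vapply(uregions, function(r) max(abs(tstat[regions == r])), numeric(1))
  uregions[order(-score, uregions)][seq_len(k)]
}

#' Restrict a feature table to a region set
#'
#' Keeps the features (all modalities) of the given regions; used to build
#' the multimodal table over a data-driven region selection.
#'
#' @param table a [FeatureTable-class].
#' @param regions character vector of region names to keep.
#' @return A [FeatureTable-class] with the retained features.
#' @export
subsetRegions <- function(table, regions) {
  keep <- as.character(SummarizedExperiment::rowData(table)$region) %in% regions
  if (!any(keep)) stop("no features match the requested regions")
  table[keep, ]
}
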
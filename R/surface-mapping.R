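## Surface mapping: linked-vertex intensity profiles, surface uptake maps,
## and the surface-based partial-volume correction (csFDG).

#' Intensity profiles along linked-vertex segments
#'
#' For every linked vertex pair, samples a volume at 6 points spaced at
#' fractions \{0, 0.2, 0.4, 0.6, 0.8, 1\} of the inner-to-outer segment
#' (the inner WM/GM vertex, four intermediate vertices from dividing the
#' segment into five equal proportions, and the outer GM/CSF vertex), each
#' by trilinear interpolation in world space.
#'
#' @param pair a [SurfacePair-class].
#' @param vol the [VolumeImage-class] to sample.
#' @return Numeric `n x 6` matrix; column j holds the samples at fraction
#'   `(j-1)/5`.
#' @export
sampleProfiles <- function(pair, vol) {
  stopifnot(is(pair, "SurfacePair"))
  vi <- vertices(innerSurface(pair))
  vo <- vertices(outerSurface(pair))
  fr <- seq(0, 1, by = 0.2)
  out <- matrix(NA_real_, nrow(vi), length(fr))
  for (j in seq_along(fr)) {
    pts <- vi + fr[j] * (vo - vi)
    out[, j] <- tryCatch(trilinearSample(vol, pts), error = function(e)
      stop(sprintf("profile sample at fraction %.1f failed: %s",
                   fr[j], conditionMessage(e)), call. = FALSE))
  }
  colnames(out) <- sprintf("f%.1f", fr)
  out
}

#' Surface map from intensity profiles
#'
#' The per-vertex mean of the 6 profile samples (both boundary vertices and
#' the 4 intermediate vertices). Applied to a DVR uptake volume this yields
#' sFDG; applied to the smoothed weighted-PVE volume it yields swPVE.
#'
#' @param profiles `n x 6` matrix from [sampleProfiles()].
#' @param units unit tag for the resulting map.
#' @return A [VertexScalarMap-class].
#' @export
surfaceMap <- function(profiles, units = "ratio") {
  stopifnot(is.matrix(profiles), ncol(profiles) == 6L)
  VertexScalarMap(rowMeans(profiles), units = units)
}

#' Surface-based partial-volume correction
#'
#' Produces the corrected surface uptake map (csFDG) by dividing the surface
#' FDG map by the surface weighted-PVE map after diffusion smoothing with a
#' 20 mm FWHM filter. By default both fields are smoothed before the
#' division (dividing a smoothed numerator by an unsmoothed denominator
#' would reintroduce high-frequency partial-volume structure);
#' `smoothTarget = "numerator"` preserves the alternative reading in which
#' only the uptake map is smoothed.
#'
#' Vertices where the smoothed swPVE falls below `epsilon` carry too little
#' effective tissue for a stable ratio and are flagged NA rather than
#' divided; if more than 10\% of vertices are flagged the tissue model is
#' considered broken and an error is raised.
#'
#' @param sfdg [VertexScalarMap-class] of surface uptake (sFDG).
#' @param swpve [VertexScalarMap-class] of surface weighted PVE (swPVE).
#' @param mesh the [TriangleMesh-class] both maps live on (smoothing domain).
#' @param fwhm diffusion-smoothing FWHM in mm (default 20).
#' @param epsilon minimum smoothed swPVE for division (default 0.05).
#' @param smoothTarget `"both"` (default) or `"numerator"`.
#' @return A [VertexScalarMap-class] (csFDG), NA at flagged vertices.
#' @export
partialVolumeCorrect <- function(sfdg, swpve, mesh, fwhm = 20,
                                 epsilon = 0.05,
                                 smoothTarget = c("both", "numerator")) {
  smoothTarget <- match.arg(smoothTarget)
  sf <- if (is(sfdg, "VertexScalarMap")) mapValues(sfdg) else as.numeric(sfdg)
  sp <- if (is(swpve, "VertexScalarMap")) mapValues(swpve) else as.numeric(swpve)
  if (length(sf) != length(sp))
    stop(sprintf("sFDG and swPVE lengths differ: %d vs %d",
                 length(sf), length(sp)))
  num <- mapValues(diffusionSmooth(mesh, sf, fwhm))
  den <- if (smoothTarget == "both") mapValues(diffusionSmooth(mesh, sp, fwhm)) else sp
  low <- den < epsilon
  if (mean(low) > 0.10)
    stop(sprintf(paste("partial-volume correction failed: smoothed swPVE < %g",
                       "at %.1f%% of vertices (broken tissue model?)"),
                 epsilon, 100 * mean(low)))
  out <- num / den
  out[low] <- NA_real_
  VertexScalarMap(out, units = "ratio")
}

#' End-to-end regional surface features for one subject
#'
#' Orchestrates the full surface pipeline: weighted PVE from the tissue
#' fractions, 6 mm Gaussian smoothing of the wPVE volume (to match PET
#' resolution), linked-vertex profile sampling of the (unsmoothed) DVR
#' volume and the smoothed wPVE volume, the 6-sample surface means (sFDG,
#' swPVE), 20 mm diffusion-smoothed partial-volume correction (csFDG), and
#' regional aggregation; plus t-link thickness and its regional means.
#'
#' @param pair a [SurfacePair-class].
#' @param labels a [SurfaceLabelMap-class] on the pair's vertices.
#' @param dvr the intensity-normalized uptake [VolumeImage-class].
#' @param tissues a [TissueFractions-class] co-registered with `dvr`.
#' @param petFwhm FWHM (mm) of the Gaussian applied to the wPVE volume to
#'   match the PET point-spread function (default 6).
#' @param surfFwhm FWHM (mm) of the surface diffusion smoothing applied
#'   before the PVC division (default 20).
#' @param epsilon swPVE division floor (default 0.05).
#' @param smoothTarget see [partialVolumeCorrect()].
#' @return List with named numeric vectors `thickness` and `csfdg`
#'   (regional means over the same region set), plus the per-vertex maps
#'   `thicknessMap`, `sfdgMap`, `swpveMap`, `csfdgMap` and the uncorrected
#'   regional means `sfdg`.
#' @export
buildSurfaceFeatures <- function(pair, labels, dvr, tissues,
                                 petFwhm = 6, surfFwhm = 20, epsilon = 0.05,
                                 smoothTarget = "both") {
  wpve <- gaussianSmooth(weightedPVE(tissues), petFwhm)
  mesh <- innerSurface(pair)
  sfdg <- surfaceMap(sampleProfiles(pair, dvr), units = "DVR")
  swpve <- surfaceMap(sampleProfiles(pair, wpve), units = "wPVE")
  csfdg <- partialVolumeCorrect(sfdg, swpve, mesh, fwhm = surfFwhm,
                                epsilon = epsilon, smoothTarget = smoothTarget)
  thick <- linkThickness(pair)
  thickness_means <- regionalMean(thick, labels)
  csfdg_means <- regionalMean(csfdg, labels)
  common <- intersect(names(thickness_means), names(csfdg_means))
  list(thickness = thickness_means[common],
       csfdg = csfdg_means[common],
       sfdg = regionalMean(sfdg, labels)[common],
       thicknessMap = thick, sfdgMap = sfdg, swpveMap = swpve,
       csfdgMap = csfdg)
}
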
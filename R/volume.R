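## Volumetric operations: weighted partial-volume estimation, Gaussian
## smoothing, cerebellar reference (DVR) normalization, trilinear sampling
## in world coordinates, and masked statistics.

.sameGrid <- function(a, b, what = "volumes") {
  if (!identical(dim(imageData(a)), dim(imageData(b))))
    stop(sprintf("%s have mismatched grid shapes: %s vs %s", what,
                 paste(dim(imageData(a)), collapse = "x"),
                 paste(dim(imageData(b)), collapse = "x")))
  if (max(abs(imageAffine(a) - imageAffine(b))) > 1e-6)
    stop(sprintf("%s have mismatched affines", what))
  invisible(TRUE)
}

#' Weighted partial-volume-estimation map
#'
#' Collapses GM/WM/CSF tissue fractions into a single expected-uptake
#' weighting under the model that CSF takes up no tracer and WM uptake is
#' one fourth that of GM:
#' \deqn{wPVE = 1 \cdot GM + 0.25 \cdot WM + 0 \cdot CSF.}
#'
#' @param tissues a [TissueFractions-class].
#' @param wmWeight WM-to-GM uptake ratio (default 0.25).
#' @return A [VolumeImage-class] on the same grid, values in \[0, 1\].
#' @export
weightedPVE <- function(tissues, wmWeight = 0.25) {
  stopifnot(is(tissues, "TissueFractions"))
  VolumeImage(tissues@gm@data + wmWeight * tissues@wm@data,
              affine = imageAffine(tissues@gm), units = "wPVE")
}

## 1-D zero-padded Gaussian convolution matrix for one axis.
.gaussKernelMatrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  halfw <- max(1L, ceiling(4 * sigma_vox))
  x <- (-halfw):halfw
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k <- k / sum(k)
  K <- matrix(0, n, n)
  for (o in seq_along(x)) {
    rows <- seq_len(n) + x[o]
    ok <- rows >= 1 & rows <= n
    K[cbind(rows[ok], seq_len(n)[ok])] <- K[cbind(rows[ok], seq_len(n)[ok])] + k[o]
  }
  K
}

#' Isotropic Gaussian smoothing of a volume
#'
#' Separable Gaussian filter with \eqn{\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2})}
#' millimetres on each axis; anisotropic voxel sizes are handled by
#' converting to per-axis sigmas in voxel units. Boundaries are zero-padded:
#' signal within ~4 sigma of the grid edge leaks outward, so callers should
#' keep the support of interest away from the boundary.
#'
#' @param vol a [VolumeImage-class].
#' @param fwhm kernel full width at half maximum in mm; 0 is the identity.
#' @return A smoothed [VolumeImage-class] on the same grid.
#' @export
gaussianSmooth <- function(vol, fwhm) {
  stopifnot(is(vol, "VolumeImage"))
  if (length(fwhm) != 1L || !is.finite(fwhm) || fwhm < 0)
    stop("fwhm must be a single non-negative number")
  if (fwhm == 0) return(vol)
  sigma_mm <- fwhm / (2 * sqrt(2 * log(2)))
  vdim <- sqrt(colSums(imageAffine(vol)[1:3, 1:3]^2))  # mm per voxel step
  d <- dim(vol@data)
  arr <- vol@data
  ## axis 1
  K <- .gaussKernelMatrix(d[1], sigma_mm / vdim[1])
  arr <- array(K %*% matrix(arr, d[1]), d)
  ## axis 2
  K <- .gaussKernelMatrix(d[2], sigma_mm / vdim[2])
  arr <- aperm(array(K %*% matrix(aperm(arr, c(2, 1, 3)), d[2]),
                     c(d[2], d[1], d[3])), c(2, 1, 3))
  ## axis 3
  K <- .gaussKernelMatrix(d[3], sigma_mm / vdim[3])
  arr <- aperm(array(K %*% matrix(aperm(arr, c(3, 1, 2)), d[3]),
                     c(d[3], d[1], d[2])), c(2, 3, 1))
  VolumeImage(arr, affine = imageAffine(vol), units = vol@units)
}

#' Reference-region (DVR-style) intensity normalization
#'
#' Divides every voxel by the mean uptake inside a reference mask — here the
#' cerebellum, where glucose metabolism is relatively preserved in AD — so
#' the output is a distribution-volume-ratio-style image whose mean inside
#' the mask is exactly 1.
#'
#' @param pet a [VolumeImage-class] of tracer uptake.
#' @param cerebellum a [BinaryMask-class] aligned with `pet`.
#' @return A normalized [VolumeImage-class].
#' @export
dvrNormalize <- function(pet, cerebellum) {
  stopifnot(is(pet, "VolumeImage"), is(cerebellum, "BinaryMask"))
  .sameGrid(pet, cerebellum, "pet and reference mask")
  inmask <- cerebellum@data > 0
  if (!any(inmask)) stop("reference mask is empty")
  ref <- mean(pet@data[inmask])
  if (!is.finite(ref) || ref <= 0)
    stop(sprintf("reference mean %.4g is not a valid normalizer", ref))
  VolumeImage(pet@data / ref, affine = imageAffine(pet), units = "DVR")
}

#' Trilinear sampling at world coordinates
#'
#' Interpolates voxel values at arbitrary world-mm points: points are mapped
#' to continuous 0-based voxel indices through the inverse affine and
#' interpolated trilinearly from the 8 surrounding voxel centers. Points
#' outside the convex hull of voxel centers are an error — no silent
#' extrapolation.
#'
#' @param vol a [VolumeImage-class].
#' @param points numeric `n x 3` matrix (or length-3 vector) of world mm.
#' @return Numeric vector of `n` interpolated values.
#' @export
trilinearSample <- function(vol, points) {
  stopifnot(is(vol, "VolumeImage"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  d <- dim(vol@data)
  ijk <- cbind(points, 1) %*% t(solve(imageAffine(vol)))[, 1:3]
  eps <- 1e-9
  oob <- ijk[, 1] < -eps | ijk[, 1] > d[1] - 1 + eps |
         ijk[, 2] < -eps | ijk[, 2] > d[2] - 1 + eps |
         ijk[, 3] < -eps | ijk[, 3] > d[3] - 1 + eps
  if (any(oob))
    stop(sprintf("%d sample point(s) outside the voxel-center hull (first: index %d)",
                 sum(oob), which(oob)[1]))
  i0 <- pmin(pmax(floor(ijk[, 1]), 0), d[1] - 2)
  j0 <- pmin(pmax(floor(ijk[, 2]), 0), d[2] - 2)
  k0 <- pmin(pmax(floor(ijk[, 3]), 0), d[3] - 2)
  fx <- ijk[, 1] - i0; fy <- ijk[, 2] - j0; fz <- ijk[, 3] - k0
  at <- function(di, dj, dk)
    vol@data[cbind(i0 + di + 1, j0 + dj + 1, k0 + dk + 1)]
  (1 - fx) * (1 - fy) * (1 - fz) * at(0, 0, 0) +
    fx * (1 - fy) * (1 - fz) * at(1, 0, 0) +
    (1 - fx) * fy * (1 - fz) * at(0, 1, 0) +
    (1 - fx) * (1 - fy) * fz * at(0, 0, 1) +
    fx * fy * (1 - fz) * at(1, 1, 0) +
    fx * (1 - fy) * fz * at(1, 0, 1) +
    (1 - fx) * fy * fz * at(0, 1, 1) +
    fx * fy * fz * at(1, 1, 1)
}

#' Mean value and total volume inside a mask
#'
#' @param vol a [VolumeImage-class].
#' @param mask a [BinaryMask-class] aligned with `vol`.
#' @return List with `mean` (mean voxel value over the mask) and
#'   `volume` (mask voxel count times voxel volume, mm^3).
#' @export
maskedStats <- function(vol, mask) {
  stopifnot(is(vol, "VolumeImage"), is(mask, "BinaryMask"))
  .sameGrid(vol, mask, "volume and mask")
  inmask <- mask@data > 0
  n <- sum(inmask)
  if (n == 0) stop("mask is empty: no voxels to summarize")
  list(mean = mean(vol@data[inmask]), volume = n * voxelVolume(vol))
}
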
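## Synthetic imaging phantom: a spherical-shell cortex with linked inner
## and outer icosphere surfaces, 39 direction-Voronoi regions, supersampled
## tissue fractions, PSF-blurred PET activity, and the reference masks —
## all with known ground truth.

## n nearly uniform unit directions (Fibonacci spiral), used as region seeds
.fibonacciSphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Phantom specification
#'
#' Parameters of the synthetic imaging subject. The cortex is a spherical
#' shell: inner (WM/GM) boundary at `innerRadius`, outer (GM/CSF) boundary
#' offset radially by the per-region thickness; 39 regions are the
#' direction-Voronoi cells of near-uniform seed directions. A separate
#' uptake-1 sphere stands in for the cerebellar reference and a small
#' interior ellipsoid for the hippocampus.
#'
#' @param gridDim length-3 integer grid shape (default 64^3).
#' @param voxelSize isotropic voxel size in mm (default 3, typical PET).
#' @param innerRadius WM/GM boundary radius in mm (default 60, the scale of
#'   an adult cortex, so that regional patches are large relative to the
#'   20 mm surface smoothing kernel).
#' @param thickness per-region cortical thickness in mm: scalar or named
#'   vector over [cortexRegions()] (default 2).
#' @param uptake per-region true GM uptake in DVR units (default 1.2).
#' @param wmFraction WM-to-GM uptake ratio (default 0.25).
#' @param hipUptake true hippocampal uptake (default 1.1).
#' @param cerebUptake reference-region uptake (default 1.0).
#' @param psfFwhm scanner point-spread FWHM in mm (default 6).
#' @param noiseSd additive Gaussian noise SD in DVR units (default 0.01).
#' @param subdivisions icosphere subdivision level (default 4: 2562 vertices).
#' @param supersample per-axis subsampling factor for occupancy fractions
#'   (default 3).
#' @param seed integer seed fixing all randomness.
#' @return A list of validated phantom parameters (class `phantomSpec`).
#' @export
phantomSpec <- function(gridDim = c(64L, 64L, 64L), voxelSize = 3,
                        innerRadius = 60, thickness = 2, uptake = 1.2,
                        wmFraction = 0.25, hipUptake = 1.1,
                        cerebUptake = 1.0, psfFwhm = 6, noiseSd = 0.01,
                        subdivisions = 4L, supersample = 3L, seed = 1L) {
  regions <- cortexRegions()
  expand <- function(x, what) {
    if (length(x) == 1L) return(stats::setNames(rep(x, 39), regions))
    if (is.null(names(x)) || !all(regions %in% names(x)))
      stop(sprintf("%s must be a scalar or named over all 39 regions", what))
    x[regions]
  }
  thickness <- expand(thickness, "thickness")
  uptake <- expand(uptake, "uptake")
  if (any(thickness <= 0)) stop("thicknesses must be > 0")
  if (psfFwhm < 0 || noiseSd < 0) stop("psfFwhm and noiseSd must be >= 0")
  extent <- (gridDim - 1) * voxelSize
  cc <- extent * c(0.5, 0.5, 0.59)          # cortex center, shifted up
  cerebC <- c(extent[1:2] * 0.5, 24)        # reference sphere, below
  cerebR <- 12
  rOutMax <- innerRadius + max(thickness)
  margin <- 2 * psfFwhm
  if (any(cc - rOutMax - margin < 0) || any(cc + rOutMax + margin > extent) ||
      any(cerebC - cerebR - margin < 0) || any(cerebC + cerebR + margin > extent))
    stop("phantom geometry overflows the grid (need a 2 x PSF margin)")
  if (cc[3] - rOutMax - (cerebC[3] + cerebR) < psfFwhm)
    stop("cortex and reference spheres too close for the PSF")
  structure(list(
    gridDim = as.integer(gridDim), voxelSize = voxelSize,
    innerRadius = innerRadius, thickness = thickness, uptake = uptake,
    wmFraction = wmFraction, hipUptake = hipUptake,
    cerebUptake = cerebUptake, psfFwhm = psfFwhm, noiseSd = noiseSd,
    subdivisions = as.integer(subdivisions),
    supersample = as.integer(supersample), seed = as.integer(seed),
    cortexCenter = cc, cerebCenter = cerebC, cerebRadius = cerebR,
    hipCenter = cc + c(20, 0, 0), hipAxes = c(18, 10, 8),
    seeds = .fibonacciSphere(39)), class = "phantomSpec")
}

## classify arbitrary world points: tissue (1 GM, 2 WM, 3 CSF), cortical
## region id, noise-free activity
.phantomClassify <- function(pts, spec) {
  rel <- sweep(pts, 2, spec$cortexCenter)
  r <- sqrt(rowSums(rel^2))
  dirs <- rel / pmax(r, 1e-12)
  regid <- max.col(dirs %*% t(spec$seeds), ties.method = "first")
  rOut <- spec$innerRadius + unname(spec$thickness[regid])
  tissue <- rep(3L, nrow(pts))                      # CSF
  tissue[r < spec$innerRadius] <- 2L                # WM
  isCortexGM <- r >= spec$innerRadius & r < rOut
  tissue[isCortexGM] <- 1L
  activity <- numeric(nrow(pts))
  activity[isCortexGM] <- unname(spec$uptake[regid[isCortexGM]])
  inWM <- tissue == 2L
  activity[inWM] <- spec$wmFraction * unname(spec$uptake[regid[inWM]])
  ## hippocampus: GM-like ellipsoid inside the WM sphere
  hq <- sqrt(rowSums(sweep(sweep(pts, 2, spec$hipCenter), 2, spec$hipAxes, "/")^2))
  inHip <- hq < 1
  tissue[inHip] <- 1L
  activity[inHip] <- spec$hipUptake
  ## cerebellar reference sphere (GM, uptake cerebUptake)
  rc <- sqrt(rowSums(sweep(pts, 2, spec$cerebCenter)^2))
  inCereb <- rc < spec$cerebRadius
  tissue[inCereb] <- 1L
  activity[inCereb] <- spec$cerebUptake
  list(tissue = tissue, regid = regid, activity = activity,
       r = r, rc = rc, hq = hq, isCortexGM = isCortexGM & !inHip & !inCereb)
}

#' Generate a synthetic imaging subject
#'
#' Builds a fully co-registered synthetic subject from a [phantomSpec()]:
#' linked inner/outer cortical icospheres with per-region radial thickness,
#' a 39-region surface label map, GM/WM/CSF occupancy fractions computed by
#' per-voxel supersampling, a PET volume (true activity `uptake` in cortical
#' GM, `wmFraction * uptake` in WM, 0 in CSF, convolved with the scanner PSF
#' plus additive Gaussian noise), a native-space region label volume, and
#' cerebellum / hippocampus / intracranial masks. The returned `truth`
#' carries the regional ground truth the pipeline should recover. The
#' cerebellum reference mask is eroded by one PSF FWHM so the reference mean
#' is not depressed by boundary spill.
#'
#' @param spec a [phantomSpec()].
#' @return List with `pair` ([SurfacePair-class]), `labels`
#'   ([SurfaceLabelMap-class]), `tissues` ([TissueFractions-class]), `pet`
#'   ([VolumeImage-class]), `labelVol` (region-id volume), `masks` (list of
#'   [BinaryMask-class]: `cerebellum`, `hippocampus`, `icv`), `truth`, and
#'   the `spec`.
#' @export
generatePhantom <- function(spec = phantomSpec()) {
  stopifnot(inherits(spec, "phantomSpec"))
  d <- spec$gridDim; vs <- spec$voxelSize
  affine <- diag(c(vs, vs, vs, 1))
  n <- prod(d)
  xs <- (seq_len(d[1]) - 1) * vs
  ys <- (seq_len(d[2]) - 1) * vs
  zs <- (seq_len(d[3]) - 1) * vs
  X <- array(xs, d)
  Y <- array(rep(ys, each = d[1]), d)
  Z <- array(rep(zs, each = d[1] * d[2]), d)
  cc <- spec$cortexCenter
  r <- sqrt((X - cc[1])^2 + (Y - cc[2])^2 + (Z - cc[3])^2)
  rc <- sqrt((X - spec$cerebCenter[1])^2 + (Y - spec$cerebCenter[2])^2 +
             (Z - spec$cerebCenter[3])^2)
  hq <- sqrt(((X - spec$hipCenter[1]) / spec$hipAxes[1])^2 +
             ((Y - spec$hipCenter[2]) / spec$hipAxes[2])^2 +
             ((Z - spec$hipCenter[3]) / spec$hipAxes[3])^2)
  rOutMax <- spec$innerRadius + max(spec$thickness)
  bw <- vs * 0.9                     # half voxel diagonal, interface band
  near <- which(r < rOutMax + 2 * bw | rc < spec$cerebRadius + 2 * bw |
                hq < 1 + 2 * bw / min(spec$hipAxes))
  pts <- cbind(X[near], Y[near], Z[near])
  cls <- .phantomClassify(pts, spec)

  gm <- array(0, d); wm <- array(0, d); csf <- array(1, d)
  gm[near] <- as.numeric(cls$tissue == 1L)
  wm[near] <- as.numeric(cls$tissue == 2L)
  csf[near] <- as.numeric(cls$tissue == 3L)
  act <- array(0, d)
  act[near] <- cls$activity
  ## native parcellation: the full cortical shell band (captures partial-GM
  ## boundary voxels so regional GM fractions integrate to the shell volume)
  rOutHere <- spec$innerRadius + unname(spec$thickness[cls$regid])
  band <- cls$r > spec$innerRadius - vs & cls$r < rOutHere + vs
  labarr <- array(0L, d)
  labarr[near[band]] <- cls$regid[band]

  ## supersample voxels straddling an interface
  onb <- abs(cls$r - spec$innerRadius) < bw | abs(cls$r - rOutHere) < bw |
         abs(cls$rc - spec$cerebRadius) < bw |
         abs(cls$hq - 1) * min(spec$hipAxes) < bw
  if (any(onb)) {
    S <- spec$supersample
    off <- ((seq_len(S) - 0.5) / S - 0.5) * vs
    offs <- as.matrix(expand.grid(off, off, off))
    nb <- sum(onb); ns <- nrow(offs)
    bpts <- pts[onb, , drop = FALSE]
    sub <- bpts[rep(seq_len(nb), each = ns), ] + offs[rep(seq_len(ns), nb), ]
    scls <- .phantomClassify(sub, spec)
    grp <- rep(seq_len(nb), each = ns)
    idxb <- near[onb]
    gm[idxb] <- rowsum(as.numeric(scls$tissue == 1L), grp)[, 1] / ns
    wm[idxb] <- rowsum(as.numeric(scls$tissue == 2L), grp)[, 1] / ns
    csf[idxb] <- rowsum(as.numeric(scls$tissue == 3L), grp)[, 1] / ns
    act[idxb] <- rowsum(scls$activity, grp)[, 1] / ns
  }
  tissues <- TissueFractions(VolumeImage(gm, affine, "fraction"),
                             VolumeImage(wm, affine, "fraction"),
                             VolumeImage(csf, affine, "fraction"))

  pet <- gaussianSmooth(VolumeImage(act, affine, "activity"), spec$psfFwhm)
  if (spec$noiseSd > 0) {
    set.seed(spec$seed)
    pet@data <- pet@data + stats::rnorm(n, 0, spec$noiseSd)
  }

  ## masks at voxel centers; cerebellar reference eroded by one PSF FWHM
  cerebMask <- BinaryMask(array(as.numeric(rc <= spec$cerebRadius - spec$psfFwhm), d), affine)
  hipMask <- BinaryMask(array(as.numeric(hq < 1), d), affine)
  icvMask <- BinaryMask(array(as.numeric(r <= rOutMax + 6 | rc <= spec$cerebRadius + 4), d),
                        affine)

  ## linked surfaces: concentric icospheres with per-region radial offsets
  inner <- icosphere(spec$subdivisions, spec$innerRadius, cc)
  vdir <- sweep(vertices(inner), 2, cc)
  vdir <- vdir / sqrt(rowSums(vdir^2))
  vreg <- max.col(vdir %*% t(spec$seeds), ties.method = "first")
  outer <- TriangleMesh(vertices(inner) + vdir * unname(spec$thickness[vreg]),
                        faces(inner))
  pair <- SurfacePair(inner, outer)
  labels <- SurfaceLabelMap(vreg, surfaceLexicon())

  ## ground truth; solid-angle fractions estimated on a fixed fine mesh so
  ## the truth's accuracy does not depend on the surface resolution in use
  fine <- icosphere(4L, 1)
  fdir <- vertices(fine)
  freg <- max.col(fdir %*% t(spec$seeds), ties.method = "first")
  av <- vertexAreas(fine)
  omega <- as.numeric(rowsum(av, freg) / sum(av))
  shellVol <- omega * (4 * pi / 3) *
    ((spec$innerRadius + unname(spec$thickness))^3 - spec$innerRadius^3)
  truth <- list(uptake = spec$uptake, thickness = spec$thickness,
                hipUptake = spec$hipUptake,
                hipVolume = (4 * pi / 3) * prod(spec$hipAxes),
                cerebUptake = spec$cerebUptake,
                regionSolidAngle = stats::setNames(omega, cortexRegions()),
                gmShellVolume = stats::setNames(shellVol, cortexRegions()))

  list(pair = pair, labels = labels, tissues = tissues, pet = pet,
       labelVol = VolumeImage(labarr + 0, affine, "region-id"),
       masks = list(cerebellum = cerebMask, hippocampus = hipMask,
                    icv = icvMask),
       truth = truth, spec = spec)
}
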
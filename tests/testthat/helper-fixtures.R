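# Shared fixtures built in code: tiny meshes, analytic volumes, small tables.

# a minimal valid mesh from explicit vertices (single triangle per 3 vertices)
miniMesh <- function(v) {
  v <- as.matrix(v)
  TriangleMesh(v, matrix(seq_len(nrow(v))[1:3], 1, 3))
}

# volume holding the affine field a + b x + c y + d z at voxel centers
affineFieldVolume <- function(coef = c(0, 1, 0, 0), dim = c(9, 9, 9),
                              voxel = 1, origin = c(0, 0, 0)) {
  aff <- diag(c(voxel, voxel, voxel, 1))
  aff[1:3, 4] <- origin
  xs <- origin[1] + (seq_len(dim[1]) - 1) * voxel
  ys <- origin[2] + (seq_len(dim[2]) - 1) * voxel
  zs <- origin[3] + (seq_len(dim[3]) - 1) * voxel
  X <- array(xs, dim)
  Y <- array(rep(ys, each = dim[1]), dim)
  Z <- array(rep(zs, each = dim[1] * dim[2]), dim)
  VolumeImage(coef[1] + coef[2] * X + coef[3] * Y + coef[4] * Z, aff)
}

# Gaussian two-class feature table with a given mean separation on column 1
gaussianTable <- function(n0 = 20, n1 = 20, d = 2, delta = 0, seed = 1,
                          labels = c("NC", "AD")) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n0 * d), n0, d),
             sweep(matrix(rnorm(n1 * d), n1, d), 2, c(delta, rep(0, d - 1)), "+"))
  regions <- allRegions()[seq_len(d)]
  colnames(X) <- paste0("FDG: ", regions)
  FeatureTable(X, diagnosis = rep(labels, c(n0, n1)),
               modality = rep("FDG", d), source = rep("surface", d),
               region = regions)
}

# complete per-subject regional feature bundle for table assembly
makeSubject <- function(shift = 0) {
  regs <- cortexRegions()
  list(thickness = stats::setNames(rep(2.5, 39) + shift, regs),
       csfdg = stats::setNames(rep(1.2, 39) + shift, regs),
       hipVolume = 0.0025 + shift, hipUptake = 1.1 + shift,
       gmVolume = stats::setNames(rep(0.001, 39) + shift, regs),
       volUptake = stats::setNames(rep(1.15, 39) + shift, regs))
}

# labeled icosphere: k bands of latitude as regions
bandLabels <- function(mesh, k = 4) {
  z <- vertices(mesh)[, 3]
  br <- seq(min(z) - 1e-9, max(z) + 1e-9, length.out = k + 1)
  ids <- as.integer(cut(z, br))
  SurfaceLabelMap(ids, stats::setNames(paste0("band", seq_len(k)),
                                       as.character(seq_len(k))))
}
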
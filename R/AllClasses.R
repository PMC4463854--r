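## S4 data model: triangle meshes, linked surface pairs, per-vertex maps,
## volumetric images, tissue fractions, feature tables and fitted models.

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Triangle mesh
#'
#' A triangulated surface: an `n x 3` matrix of vertex coordinates in mm and
#' an `m x 3` integer matrix of 1-based vertex indices per face.
#'
#' @slot vertices numeric matrix, one row per vertex, columns x/y/z in mm.
#' @slot faces integer matrix, one row per triangle.
#'
#' @export
setClass("TriangleMesh",
  representation(vertices = "matrix", faces = "matrix"))

setValidity("TriangleMesh", function(object) {
  v <- object@vertices; f <- object@faces
  if (ncol(v) != 3L) return("vertices must have 3 columns")
  if (ncol(f) != 3L) return("faces must have 3 columns")
  if (!all(is.finite(v))) return("vertex coordinates must be finite")
  fi <- as.integer(f)
  if (any(fi < 1L) || any(fi > nrow(v)))
    return(sprintf("face indices must lie in [1, %d]", nrow(v)))
  if (any(f[, 1] == f[, 2] | f[, 1] == f[, 3] | f[, 2] == f[, 3]))
    return("degenerate face: repeated vertex index within a triangle")
  TRUE
})

#' Construct a TriangleMesh
#'
#' @param vertices numeric `n x 3` matrix of coordinates (mm).
#' @param faces integer `m x 3` matrix of 1-based vertex indices.
#' @return A [TriangleMesh-class] object.
#' @export
TriangleMesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices); faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL; dimnames(faces) <- NULL
  new("TriangleMesh", vertices = vertices, faces = faces)
}

#' @describeIn TriangleMesh-class Vertex coordinate matrix.
#' @param x a `TriangleMesh`.
#' @export
setMethod("vertices", "TriangleMesh", function(x) x@vertices)

#' @describeIn TriangleMesh-class Face index matrix.
#' @export
setMethod("faces", "TriangleMesh", function(x) x@faces)

#' @describeIn TriangleMesh-class Number of vertices.
#' @export
setMethod("nVertices", "TriangleMesh", function(x) nrow(x@vertices))

setMethod("show", "TriangleMesh", function(object) {
  cat(sprintf("TriangleMesh: %d vertices, %d faces\n",
              nrow(object@vertices), nrow(object@faces)))
})

#' Linked inner/outer cortical surface pair
#'
#' Inner (WM/GM boundary) and outer (GM/CSF boundary) meshes with identical
#' face topology; vertex i of the inner mesh is the anatomical link partner
#' of vertex i of the outer mesh, so per-vertex quantities (thickness,
#' intensity profiles) are defined along linked-vertex segments.
#'
#' @slot inner,outer [TriangleMesh-class] objects sharing topology.
#' @export
setClass("SurfacePair",
  representation(inner = "TriangleMesh", outer = "TriangleMesh"))

setValidity("SurfacePair", function(object) {
  ni <- nVertices(object@inner); no <- nVertices(object@outer)
  if (ni != no)
    return(sprintf("inner and outer vertex counts differ: %d vs %d", ni, no))
  if (!identical(dim(object@inner@faces), dim(object@outer@faces)) ||
      !all(object@inner@faces == object@outer@faces))
    return("inner and outer face topology must be identical")
  TRUE
})

#' Construct a SurfacePair
#' @param inner,outer [TriangleMesh-class] objects with identical topology.
#' @return A [SurfacePair-class].
#' @export
SurfacePair <- function(inner, outer) new("SurfacePair", inner = inner, outer = outer)

#' @describeIn SurfacePair-class Inner (WM/GM) mesh.
#' @param x a `SurfacePair`.
#' @export
setMethod("innerSurface", "SurfacePair", function(x) x@inner)

#' @describeIn SurfacePair-class Outer (GM/CSF) mesh.
#' @export
setMethod("outerSurface", "SurfacePair", function(x) x@outer)

#' @describeIn SurfacePair-class Number of linked vertices.
#' @export
setMethod("nVertices", "SurfacePair", function(x) nVertices(x@inner))

setMethod("show", "SurfacePair", function(object) {
  cat(sprintf("SurfacePair: %d linked vertices, %d faces\n",
              nVertices(object@inner), nrow(object@inner@faces)))
})

#' Per-vertex scalar map
#'
#' One real value per vertex of a surface, with a free-text unit tag
#' ("mm", "ratio", ...). Values may be NA where a vertex has been flagged
#' invalid (e.g. near-zero tissue under partial-volume correction); NA is
#' the missing-value marker, all non-missing values must be finite.
#'
#' @slot values numeric vector, one entry per vertex.
#' @slot units character unit tag.
#' @export
setClass("VertexScalarMap",
  representation(values = "numeric", units = "character"))

setValidity("VertexScalarMap", function(object) {
  if (length(object@units) != 1L) return("units must be a single string")
  v <- object@values
  if (any(!is.na(v) & !is.finite(v)))
    return("non-missing map values must be finite")
  TRUE
})

#' Construct a VertexScalarMap
#' @param values numeric vector, one value per vertex (NA = flagged invalid).
#' @param units single string unit tag.
#' @return A [VertexScalarMap-class].
#' @export
VertexScalarMap <- function(values, units = "dimensionless")
  new("VertexScalarMap", values = as.numeric(values), units = units)

#' @describeIn VertexScalarMap-class Numeric values.
#' @param x a `VertexScalarMap`.
#' @export
setMethod("mapValues", "VertexScalarMap", function(x) x@values)

#' @describeIn VertexScalarMap-class Unit tag.
#' @export
setMethod("mapUnits", "VertexScalarMap", function(x) x@units)

#' @describeIn VertexScalarMap-class Number of vertices covered.
#' @export
setMethod("nVertices", "VertexScalarMap", function(x) length(x@values))

setMethod("show", "VertexScalarMap", function(object) {
  v <- object@values
  cat(sprintf("VertexScalarMap [%s]: %d vertices (%d flagged), range [%g, %g]\n",
              object@units, length(v), sum(is.na(v)),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE))))
})

#' Per-vertex region labels
#'
#' Integer region id per vertex plus a lexicon mapping ids to region names.
#' Id 0 is reserved for unlabeled vertices and never appears in the lexicon.
#'
#' @slot regionId integer vector, one id per vertex (0 = unlabeled).
#' @slot lexicon named character vector; names are the ids as strings.
#' @export
setClass("SurfaceLabelMap",
  representation(regionId = "integer", lexicon = "character"))

setValidity("SurfaceLabelMap", function(object) {
  ids <- unique(object@regionId[object@regionId != 0L])
  if (any(object@regionId < 0L)) return("region ids must be non-negative")
  missing <- setdiff(as.character(ids), names(object@lexicon))
  if (length(missing))
    return(paste("region ids missing from lexicon:", paste(missing, collapse = ", ")))
  if ("0" %in% names(object@lexicon))
    return("id 0 is reserved for unlabeled vertices")
  TRUE
})

#' Construct a SurfaceLabelMap
#' @param regionId integer vector of per-vertex region ids (0 = unlabeled).
#' @param lexicon named character vector mapping id (as string) to region name.
#' @return A [SurfaceLabelMap-class].
#' @export
SurfaceLabelMap <- function(regionId, lexicon)
  new("SurfaceLabelMap", regionId = as.integer(regionId), lexicon = lexicon)

#' @describeIn SurfaceLabelMap-class Per-vertex region ids.
#' @param x a `SurfaceLabelMap`.
#' @export
setMethod("regionIds", "SurfaceLabelMap", function(x) x@regionId)

#' @describeIn SurfaceLabelMap-class Region id to name lexicon.
#' @export
setMethod("lexicon", "SurfaceLabelMap", function(x) x@lexicon)

#' @describeIn SurfaceLabelMap-class Number of labeled vertices.
#' @export
setMethod("nVertices", "SurfaceLabelMap", function(x) length(x@regionId))

setMethod("show", "SurfaceLabelMap", function(object) {
  cat(sprintf("SurfaceLabelMap: %d vertices, %d regions (%d unlabeled vertices)\n",
              length(object@regionId), length(object@lexicon),
              sum(object@regionId == 0L)))
})

#' Volumetric scalar image
#'
#' A 3-D grid of voxel values with a 4x4 voxel-index-to-world-mm affine
#' (0-based voxel indices, NIfTI convention) and a unit tag.
#'
#' @slot data 3-D numeric array.
#' @slot affine 4x4 numeric matrix mapping 0-based (i,j,k,1) to world mm.
#' @slot units character unit tag.
#' @export
setClass("VolumeImage",
  representation(data = "array", affine = "matrix", units = "character"))

setValidity("VolumeImage", function(object) {
  if (length(dim(object@data)) != 3L) return("data must be a 3-D array")
  if (!identical(dim(object@affine), c(4L, 4L))) return("affine must be 4x4")
  if (abs(det(object@affine[1:3, 1:3])) < 1e-12) return("affine is singular")
  if (!all(is.finite(object@data))) return("voxel values must be finite")
  TRUE
})

#' Construct a VolumeImage
#' @param data 3-D numeric array of voxel values.
#' @param affine 4x4 voxel-to-world (mm) affine; 0-based voxel indices.
#' @param units single string unit tag.
#' @return A [VolumeImage-class].
#' @export
VolumeImage <- function(data, affine = diag(4), units = "dimensionless") {
  new("VolumeImage", data = data, affine = affine, units = units)
}

#' @describeIn VolumeImage-class Voxel array.
#' @param x a `VolumeImage`.
#' @export
setMethod("imageData", "VolumeImage", function(x) x@data)

#' @describeIn VolumeImage-class Voxel-to-world affine.
#' @export
setMethod("imageAffine", "VolumeImage", function(x) x@affine)

#' @describeIn VolumeImage-class Volume of one voxel in mm^3.
#' @export
setMethod("voxelVolume", "VolumeImage", function(x) abs(det(x@affine[1:3, 1:3])))

setMethod("show", "VolumeImage", function(object) {
  d <- dim(object@data)
  cat(sprintf("%s [%s]: %d x %d x %d voxels (%.3g mm^3/voxel), range [%g, %g]\n",
              class(object), object@units, d[1], d[2], d[3],
              voxelVolume(object), min(object@data), max(object@data)))
})

#' Binary mask volume
#'
#' A [VolumeImage-class] whose voxel values are restricted to 0/1.
#' @export
setClass("BinaryMask", contains = "VolumeImage")

setValidity("BinaryMask", function(object) {
  if (!all(object@data %in% c(0, 1))) return("mask values must be 0 or 1")
  TRUE
})

#' Construct a BinaryMask
#' @param data 3-D array of 0/1 (logical is coerced).
#' @param affine 4x4 voxel-to-world affine.
#' @return A [BinaryMask-class].
#' @export
BinaryMask <- function(data, affine = diag(4)) {
  storage.mode(data) <- "double"
  new("BinaryMask", data = data, affine = affine, units = "binary")
}

#' GM/WM/CSF tissue fraction volumes
#'
#' Three co-registered partial-volume-fraction images giving, per voxel, the
#' portion occupied by gray matter, white matter and cerebrospinal fluid.
#' Fractions are in \[0,1\] and sum to at most 1 (+1e-6) per voxel; sums
#' overshooting the tolerance are rescaled at construction with a warning,
#' since upstream tissue estimators routinely overshoot slightly.
#'
#' @slot gm,wm,csf [VolumeImage-class] fraction images on a common grid.
#' @export
setClass("TissueFractions",
  representation(gm = "VolumeImage", wm = "VolumeImage", csf = "VolumeImage"))

setValidity("TissueFractions", function(object) {
  dg <- dim(object@gm@data)
  if (!identical(dg, dim(object@wm@data)) || !identical(dg, dim(object@csf@data)))
    return("gm/wm/csf grids must share shape")
  if (max(abs(object@gm@affine - object@wm@affine)) > 1e-9 ||
      max(abs(object@gm@affine - object@csf@affine)) > 1e-9)
    return("gm/wm/csf affines must match")
  rng <- range(object@gm@data, object@wm@data, object@csf@data)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-6)
    return("tissue fractions must lie in [0, 1]")
  s <- object@gm@data + object@wm@data + object@csf@data
  if (max(s) > 1 + 1e-6)
    return(sprintf("tissue fractions sum to %.8f > 1 + 1e-6 somewhere", max(s)))
  TRUE
})

#' Construct TissueFractions
#'
#' @param gm,wm,csf [VolumeImage-class] fraction images (or bare arrays,
#'   interpreted on the `affine` grid).
#' @param affine affine used when bare arrays are given.
#' @return A [TissueFractions-class].
#' @export
TissueFractions <- function(gm, wm, csf, affine = diag(4)) {
  asvol <- function(x) if (is(x, "VolumeImage")) x else VolumeImage(x, affine, "fraction")
  gm <- asvol(gm); wm <- asvol(wm); csf <- asvol(csf)
  s <- gm@data + wm@data + csf@data
  over <- s > 1 + 1e-6
  if (any(over)) {
    warning(sprintf("tissue fractions exceed 1 at %d voxels (max sum %.6f); rescaling",
                    sum(over), max(s)))
    gm@data[over] <- gm@data[over] / s[over]
    wm@data[over] <- wm@data[over] / s[over]
    csf@data[over] <- csf@data[over] / s[over]
  }
  new("TissueFractions", gm = gm, wm = wm, csf = csf)
}

setMethod("show", "TissueFractions", function(object) {
  d <- dim(object@gm@data)
  cat(sprintf("TissueFractions: %d x %d x %d voxels; mean GM %.3f, WM %.3f, CSF %.3f\n",
              d[1], d[2], d[3], mean(object@gm@data), mean(object@wm@data),
              mean(object@csf@data)))
})

#' Subjects-by-features table for classification
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' with features as rows and subjects as columns. `rowData` carries the
#' `modality` ("MRI"/"FDG") and `source` ("surface"/"volume") tag and the
#' `region` name of every feature; `colData` carries the per-subject
#' `diagnosis` ("NC"/"MCI"/"AD"). The single assay `values` holds the real
#' feature matrix with no missing values.
#'
#' @export
setClass("FeatureTable", contains = "SummarizedExperiment")

setValidity("FeatureTable", function(object) {
  if (!"values" %in% SummarizedExperiment::assayNames(object))
    return("assay 'values' is required")
  m <- SummarizedExperiment::assay(object, "values")
  if (any(!is.finite(m))) return("feature values must be finite (no missing values)")
  rd <- SummarizedExperiment::rowData(object)
  for (col in c("modality", "source", "region"))
    if (!col %in% colnames(rd)) return(sprintf("rowData column '%s' is required", col))
  if (!all(rd$modality %in% c("MRI", "FDG")))
    return("modality tags must be 'MRI' or 'FDG'")
  if (anyDuplicated(rownames(object))) return("feature names must be unique")
  cd <- SummarizedExperiment::colData(object)
  if (!"diagnosis" %in% colnames(cd)) return("colData column 'diagnosis' is required")
  if (!all(cd$diagnosis %in% c("NC", "MCI", "AD")))
    return("diagnosis must be one of NC, MCI, AD")
  TRUE
})

#' Construct a FeatureTable
#'
#' @param values subjects x features numeric matrix with unique column names
#'   and subject identifiers as row names.
#' @param diagnosis character vector of per-subject labels in
#'   `c("NC","MCI","AD")`, aligned with the rows of `values`.
#' @param modality character vector per feature, `"MRI"` or `"FDG"`.
#' @param source character vector per feature, `"surface"` or `"volume"`.
#' @param region character vector of region names per feature.
#' @return A [FeatureTable-class] (features x subjects internally).
#' @export
FeatureTable <- function(values, diagnosis, modality, source, region) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("subj%03d", seq_len(nrow(values)))
  if (length(diagnosis) != nrow(values))
    stop("diagnosis length must equal the number of subjects")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(values = t(values)),
    rowData = S4Vectors::DataFrame(modality = modality, source = source,
                                   region = region),
    colData = S4Vectors::DataFrame(diagnosis = diagnosis,
                                   row.names = rownames(values)))
  new("FeatureTable", se)
}

#' @describeIn FeatureTable-class Subjects x features numeric matrix.
#' @param x a `FeatureTable`.
#' @export
setMethod("featureMatrix", "FeatureTable",
          function(x) t(SummarizedExperiment::assay(x, "values")))

#' @describeIn FeatureTable-class Per-subject diagnosis labels.
#' @export
setMethod("diagnosis", "FeatureTable",
          function(x) as.character(SummarizedExperiment::colData(x)$diagnosis))

#' @describeIn FeatureTable-class Per-feature modality tags.
#' @export
setMethod("modality", "FeatureTable",
          function(x) as.character(SummarizedExperiment::rowData(x)$modality))

#' @describeIn FeatureTable-class Per-feature source tags.
#' @export
setMethod("featureSource", "FeatureTable",
          function(x) as.character(SummarizedExperiment::rowData(x)$source))

setMethod("show", "FeatureTable", function(object) {
  dx <- table(diagnosis(object))
  cat(sprintf("FeatureTable: %d subjects x %d features (%s)\n",
              ncol(object), nrow(object),
              paste(sprintf("%s=%d", names(dx), dx), collapse = ", ")))
})

#' Fitted partial least squares model
#'
#' Sequentially extracted latent components (NIPALS, single 0/1 response)
#' after mean-centering: weights `W`, X-loadings `P`, response loadings `q`,
#' training scores `T`, and the inner regression coefficients linking each
#' X-score to its response score.
#'
#' @slot xMeans,yMean centering constants from training.
#' @slot weights d x A weight matrix W (unit columns).
#' @slot loadings d x A X-loading matrix P.
#' @slot yLoadings length-A response loadings q.
#' @slot innerCoef length-A inner regression coefficients (u_a on t_a).
#' @slot scores N x A training score matrix T.
#' @slot projection d x A matrix W (P'W)^-1 mapping centered x to scores.
#' @slot A integer component count.
#' @export
setClass("PlsModel",
  representation(xMeans = "numeric", yMean = "numeric", weights = "matrix",
                 loadings = "matrix", yLoadings = "numeric",
                 innerCoef = "numeric", scores = "matrix",
                 projection = "matrix", A = "integer"))

setValidity("PlsModel", function(object) {
  A <- object@A
  if (ncol(object@weights) != A || ncol(object@loadings) != A ||
      length(object@yLoadings) != A || ncol(object@scores) != A ||
      ncol(object@projection) != A)
    return("component dimensions disagree with A")
  TRUE
})

#' @describeIn PlsModel-class Number of latent components.
#' @param x a `PlsModel`.
#' @export
setMethod("nComponents", "PlsModel", function(x) x@A)

setMethod("show", "PlsModel", function(object) {
  cat(sprintf("PlsModel: %d features -> %d latent components (N = %d)\n",
              nrow(object@weights), object@A, nrow(object@scores)))
})

#' Fitted linear discriminant model (pooled covariance)
#'
#' Gaussian class-conditional model in latent space: class means for the
#' 0/1 classes, a pooled within-class covariance (with a ridge floor applied
#' when ill-conditioned), and class priors.
#'
#' @slot means 2 x K matrix of class means (row 1 = class 0, row 2 = class 1).
#' @slot pooledCov K x K pooled within-class covariance.
#' @slot priors length-2 class priors.
#' @export
setClass("LdaModel",
  representation(means = "matrix", pooledCov = "matrix", priors = "numeric"))

setValidity("LdaModel", function(object) {
  K <- ncol(object@means)
  if (nrow(object@means) != 2L) return("means must have two rows (classes 0/1)")
  if (!identical(dim(object@pooledCov), c(K, K)))
    return("pooled covariance dimension must match the means")
  if (max(abs(object@pooledCov - t(object@pooledCov))) > 1e-8)
    return("pooled covariance must be symmetric")
  if (abs(sum(object@priors) - 1) > 1e-8) return("priors must sum to 1")
  TRUE
})

setMethod("show", "LdaModel", function(object) {
  cat(sprintf("LdaModel: %d latent dims; ||mu1 - mu0|| = %.4g\n",
              ncol(object@means),
              sqrt(sum((object@means[2, ] - object@means[1, ])^2))))
})

#' PLS-LDA classifier
#'
#' A [PlsModel-class] (with PRESS-selected component count K) composed with
#' an [LdaModel-class] fitted on the training latent scores.
#'
#' @slot pls the fitted PLS step.
#' @slot lda the fitted LDA step.
#' @slot K selected latent component count (equals `pls@A`).
#' @slot classLabels the two original class labels mapped to 0/1.
#' @slot scale per-feature scale factors when autoscaling was requested
#'   (length 0 otherwise).
#' @export
setClass("PlsLdaModel",
  representation(pls = "PlsModel", lda = "LdaModel", K = "integer",
                 classLabels = "character", scale = "numeric"))

setValidity("PlsLdaModel", function(object) {
  if (object@K != object@pls@A) return("K must equal the PLS component count")
  if (length(object@classLabels) != 2L) return("two class labels required")
  TRUE
})

#' @describeIn PlsLdaModel-class Selected number of latent components.
#' @param x a `PlsLdaModel`.
#' @export
setMethod("nComponents", "PlsLdaModel", function(x) x@K)

setMethod("show", "PlsLdaModel", function(object) {
  cat(sprintf("PlsLdaModel: %s vs %s, %d features, K = %d latent components\n",
              object@classLabels[1], object@classLabels[2],
              nrow(object@pls@weights), object@K))
})
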
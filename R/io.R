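## File formats: Wavefront OBJ surfaces, plain-text vertex/label maps with a
## JSON lexicon, NIfTI-1 volumes (via RNifti), and feature-table CSVs with a
## JSON sidecar schema.

#' Read a Wavefront OBJ surface
#'
#' Parses `v` and `f` records (polygonal faces must be triangles; texture /
#' normal indices like `1/1/1` are accepted and stripped).
#'
#' @param path OBJ file.
#' @return A [TriangleMesh-class].
#' @export
readOBJ <- function(path) {
  ln <- readLines(path)
  vlines <- strsplit(trimws(ln[startsWith(ln, "v ")]), "\\s+")
  flines <- strsplit(trimws(ln[startsWith(ln, "f ")]), "\\s+")
  if (!length(vlines) || !length(flines)) stop("no vertices/faces in ", path)
  v <- do.call(rbind, lapply(vlines, function(x) as.numeric(x[2:4])))
  f <- do.call(rbind, lapply(flines, function(x) {
    if (length(x) != 4) stop("only triangular faces are supported")
    as.integer(sub("/.*", "", x[2:4]))
  }))
  TriangleMesh(v, f)
}

#' Write a Wavefront OBJ surface
#'
#' @param mesh a [TriangleMesh-class].
#' @param path output file.
#' @return `path` invisibly.
#' @export
writeOBJ <- function(mesh, path) {
  v <- vertices(mesh); f <- faces(mesh)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("v %.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  invisible(path)
}

#' Read/write a vertex scalar map as text
#'
#' One value per line (NA for flagged vertices); the unit tag is kept in a
#' `# units:` comment header.
#'
#' @param path text file.
#' @return A [VertexScalarMap-class].
#' @export
readVertexMap <- function(path) {
  ln <- readLines(path)
  units <- "dimensionless"
  hdr <- grepl("^#", ln)
  u <- sub("^# *units: *", "", ln[hdr][grepl("^# *units:", ln[hdr])])
  if (length(u)) units <- u[1]
  vals <- ln[!hdr]
  v <- rep(NA_real_, length(vals))
  ok <- vals != "NA"
  v[ok] <- as.numeric(vals[ok])
  VertexScalarMap(v, units = units)
}

#' @rdname readVertexMap
#' @param map a [VertexScalarMap-class].
#' @export
writeVertexMap <- function(map, path) {
  v <- mapValues(map)
  writeLines(c(sprintf("# units: %s", mapUnits(map)),
               ifelse(is.na(v), "NA", sprintf("%.17g", v))), path)
  invisible(path)
}

#' Read/write a surface label map
#'
#' Labels as two-column text (vertex index, region id) and the lexicon as a
#' JSON file mapping id to region name.
#'
#' @param path two-column label file.
#' @param lexiconPath JSON lexicon file (default: `path` with `.json`).
#' @return A [SurfaceLabelMap-class].
#' @export
readLabelMap <- function(path, lexiconPath = paste0(path, ".json")) {
  tab <- utils::read.table(path, col.names = c("vertex", "region"))
  ids <- integer(max(tab$vertex))
  ids[tab$vertex] <- tab$region
  lex <- unlist(jsonlite::fromJSON(lexiconPath))
  SurfaceLabelMap(ids, lex)
}

#' @rdname readLabelMap
#' @param labels a [SurfaceLabelMap-class].
#' @export
writeLabelMap <- function(labels, path, lexiconPath = paste0(path, ".json")) {
  ids <- regionIds(labels)
  utils::write.table(data.frame(vertex = seq_along(ids), region = ids),
                     path, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(as.list(lexicon(labels)), lexiconPath,
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Loads a NIfTI file (header slope/intercept applied by RNifti) into a
#' [VolumeImage-class], honoring the stored voxel-to-world affine.
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @param units unit tag to attach.
#' @return A [VolumeImage-class].
#' @export
readVolume <- function(path, units = "dimensionless") {
  img <- RNifti::readNifti(path)
  VolumeImage(array(as.numeric(img), dim(img)),
              affine = structure(RNifti::xform(img), class = NULL,
                                 code = NULL, dimnames = NULL),
              units = units)
}

#' Write a volume as NIfTI-1
#'
#' @param vol a [VolumeImage-class] (or [BinaryMask-class]).
#' @param path output file (.nii or .nii.gz).
#' @return `path` invisibly.
#' @export
writeVolume <- function(vol, path) {
  img <- RNifti::asNifti(imageData(vol))
  img <- RNifti::`sform<-`(img, structure(imageAffine(vol), code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary mask from NIfTI
#'
#' @param path NIfTI file; values are binarized at 0.5.
#' @return A [BinaryMask-class].
#' @export
readMask <- function(path) {
  v <- readVolume(path)
  BinaryMask(array(as.numeric(imageData(v) > 0.5), dim(imageData(v))),
             affine = imageAffine(v))
}

#' Write a feature table as CSV plus JSON schema
#'
#' CSV with header `subject,diagnosis,<feature columns>`; the modality,
#' source and region tags go to a JSON sidecar schema.
#'
#' @param table a [FeatureTable-class].
#' @param path CSV output path.
#' @param schemaPath JSON sidecar (default `path` with `.json`).
#' @return `path` invisibly.
#' @export
writeFeatureCSV <- function(table, path, schemaPath = paste0(path, ".json")) {
  X <- featureMatrix(table)
  df <- data.frame(subject = rownames(X), diagnosis = diagnosis(table),
                   X, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  rd <- SummarizedExperiment::rowData(table)
  jsonlite::write_json(
    list(features = colnames(X), modality = as.character(rd$modality),
         source = as.character(rd$source), region = as.character(rd$region)),
    schemaPath, auto_unbox = FALSE)
  invisible(path)
}

#' Read a feature table from CSV plus JSON schema
#'
#' @param path CSV written by [writeFeatureCSV()].
#' @param schemaPath JSON sidecar path.
#' @return A [FeatureTable-class].
#' @export
readFeatureCSV <- function(path, schemaPath = paste0(path, ".json")) {
  df <- utils::read.csv(path, check.names = FALSE)
  sch <- jsonlite::fromJSON(schemaPath)
  X <- as.matrix(df[, sch$features, drop = FALSE])
  rownames(X) <- df$subject
  FeatureTable(X, diagnosis = df$diagnosis, modality = sch$modality,
               source = sch$source, region = sch$region)
}
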
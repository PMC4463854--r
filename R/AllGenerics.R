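## Generics for the package's S4 surface, volume, feature and model classes.

#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))

#' @export
setGeneric("faces", function(x) standardGeneric("faces"))

#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))

#' @export
setGeneric("innerSurface", function(x) standardGeneric("innerSurface"))

#' @export
setGeneric("outerSurface", function(x) standardGeneric("outerSurface"))

#' @export
setGeneric("imageData", function(x) standardGeneric("imageData"))

#' @export
setGeneric("imageAffine", function(x) standardGeneric("imageAffine"))

#' @export
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))

#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' @export
setGeneric("mapUnits", function(x) standardGeneric("mapUnits"))

#' @export
setGeneric("regionIds", function(x) standardGeneric("regionIds"))

#' @export
setGeneric("lexicon", function(x) standardGeneric("lexicon"))

#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @export
setGeneric("diagnosis", function(x) standardGeneric("diagnosis"))

#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' @export
setGeneric("featureSource", function(x) standardGeneric("featureSource"))

#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))
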
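## The regional lexicon: 39 cortical surface regions plus the hippocampus,
## and the 12 predefined disease-related regions used for feature selection.

#' Cortical surface region names
#'
#' The 39 cortical regions of the surface parcellation used for regional
#' averaging of thickness and uptake maps (bilateral regions merged).
#'
#' @return Character vector of 39 region names.
#' @export
cortexRegions <- function() c(
  "angular gyrus", "inferior frontal gyrus", "inferior occipital gyrus",
  "medial occipital gyrus", "middle temporal gyrus", "parahippocampal gyrus",
  "posterior cingulate gyrus", "precuneus", "rectus gyrus",
  "superior occipital gyrus", "supramarginal gyrus",
  "superior frontal gyrus", "middle frontal gyrus", "medial frontal gyrus",
  "orbitofrontal gyrus", "precentral gyrus", "postcentral gyrus",
  "paracentral lobule", "superior parietal lobule", "inferior parietal lobule",
  "superior temporal gyrus", "inferior temporal gyrus", "fusiform gyrus",
  "temporal pole", "transverse temporal gyrus", "insula",
  "anterior cingulate gyrus", "middle cingulate gyrus", "cuneus",
  "lingual gyrus", "calcarine cortex", "rolandic operculum",
  "supplementary motor area", "olfactory cortex", "frontal pole",
  "entorhinal cortex", "subcallosal area", "occipital pole",
  "middle occipital gyrus")

#' Full 40-region lexicon
#'
#' The 39 cortical surface regions plus the hippocampus.
#' @return Character vector of 40 region names.
#' @export
allRegions <- function() c(cortexRegions(), "hippocampus")

#' Predefined disease-related regions
#'
#' The 12 regions consistently implicated in AD pathology in prior MRI and
#' FDG-PET work, fixed independently of any dataset: 11 cortical regions
#' plus the hippocampus.
#'
#' @return Character vector of 12 region names.
#' @export
predefinedRegions <- function() c(
  "angular gyrus", "inferior frontal gyrus", "inferior occipital gyrus",
  "medial occipital gyrus", "middle temporal gyrus", "parahippocampal gyrus",
  "posterior cingulate gyrus", "precuneus", "rectus gyrus",
  "superior occipital gyrus", "supramarginal gyrus", "hippocampus")

#' Surface label lexicon
#'
#' Named character vector mapping region ids "1".."39" to the cortical
#' region names, the lexicon slot of a [SurfaceLabelMap-class].
#' @return Named character vector of length 39.
#' @export
surfaceLexicon <- function()
  stats::setNames(cortexRegions(), as.character(seq_len(39)))

## canonical feature name: "<modality>: <region>"
.featureName <- function(modality, region) paste0(modality, ": ", region)

.featureRegion <- function(name) sub("^(MRI|FDG): ", "", name)

.featureModality <- function(name) sub(":.*$", "", name)

#' Feature names of the selected multimodal set
#'
#' The 24 feature names (12 predefined regions x MRI and FDG modalities)
#' of the selected-multimodal-feature (SMF) scheme.
#' @param regions region names (default the predefined 12).
#' @return Character vector, MRI features first.
#' @export
smfFeatureNames <- function(regions = predefinedRegions())
  c(.featureName("MRI", regions), .featureName("FDG", regions))
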
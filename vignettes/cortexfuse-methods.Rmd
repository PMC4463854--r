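---
title: "Surface-based partial-volume-corrected PET features and PLS-LDA classification: methods"
author: "cortexfuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cortexfuse methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

FDG-PET measures cerebral glucose metabolism at a spatial resolution (point
spread of roughly 6 mm FWHM) that is coarse relative to the 2–4 mm cortical
ribbon. Measured uptake in a thin, atrophic cortex is therefore biased low —
the partial volume effect (PVE) — exactly in the populations (Alzheimer's
disease, mild cognitive impairment) where hypometabolism and atrophy must be
separated. `cortexfuse` implements a surface-based analysis that (i) maps
PET uptake onto linked cortical surface meshes, (ii) corrects the mapped
uptake with a tissue-weighted partial-volume model, (iii) combines the
corrected uptake with t-link cortical thickness into regional multimodal
features, and (iv) classifies diagnostic pairs with a partial least squares
– linear discriminant analysis (PLS-LDA) pipeline validated by
leave-one-out cross-validation (LOOCV) and ROC analysis.

# Surface-based uptake mapping and partial-volume correction

**Inputs.** Per subject: a PET uptake volume normalized to a reference
region with preserved metabolism (the cerebellum), GM/WM/CSF
partial-volume-fraction volumes from tissue classification of the MRI, and
a pair of cortical meshes — the inner WM/GM boundary and the outer GM/CSF
boundary — with one-to-one linked vertices. Surface extraction, tissue
classification and co-registration are upstream of this package; the
synthetic phantom (below) generates all inputs co-registered.

**Reference normalization.** `dvrNormalize()` divides the uptake volume by
its mean inside the cerebellar mask, yielding a distribution-volume-ratio
(DVR) style image whose cerebellar mean is exactly 1. Only the static
reference-ratio normalization is implemented; kinetic multi-frame modeling
belongs to upstream reconstruction.

**Weighted PVE.** `weightedPVE()` collapses the three tissue fractions into
the expected-uptake weighting `wPVE = 1·GM + 0.25·WM + 0·CSF`, i.e. CSF
takes up no tracer and WM roughly one quarter of GM. The wPVE volume is
smoothed with a 6 mm FWHM Gaussian (`gaussianSmooth()`) so that it carries
the same point-spread blur as the PET image; the PET/DVR volume itself is
sampled unsmoothed, since the scanner already applied its PSF.

**Profiles and surface maps.** For every linked vertex pair,
`sampleProfiles()` takes 6 trilinear samples at fractions
{0, 0.2, 0.4, 0.6, 0.8, 1} of the inner→outer segment (the two boundary
vertices plus four intermediate vertices from dividing the segment into
five equal proportions), and `surfaceMap()` averages them. The mean — not
the maximum used by earlier surface-projection work — is used because the
locations of maximal uptake and maximal tissue density differ, which breaks
the subsequent division. Applied to the DVR volume this yields sFDG;
applied to the smoothed wPVE volume, swPVE.

**Correction.** `partialVolumeCorrect()` computes
`csFDG = smooth(sFDG) / smooth(swPVE)` with 20 mm FWHM diffusion smoothing
on the mesh. Both fields are smoothed before the division by default: a
smoothed numerator over an unsmoothed denominator would reintroduce the
high-frequency PVE structure the correction is meant to remove. The
alternative reading (smoothing only the numerator) is available via
`smoothTarget = "numerator"`. Vertices whose smoothed swPVE falls below
`epsilon = 0.05` (5% effective tissue) are flagged `NA` and excluded from
regional means rather than divided; if more than 10% of vertices are
flagged the tissue model is considered broken and the correction errors.

**Why the correction is exact in the ideal case.** If the measured PET is
`PSF * (u · wPVE)` for a spatially constant true uptake `u` and the wPVE
volume is smoothed with the same PSF, then sFDG = u · swPVE pointwise and
csFDG = u exactly — smoothing is linear, so the 20 mm surface smoothing
cancels in the ratio. Departures come from noise, discretization, spatially
varying `u`, and reference-region bias; the phantom quantifies them.

# Thickness and regional features

`linkThickness()` is the t-link metric: the Euclidean distance between
linked vertices, in mm. `regionalMean()` averages any per-vertex map over a
39-region cortical surface parcellation; the mean is unweighted across
vertices by default (an area-weighted variant sits behind
`areaWeighted = TRUE`), because the plain arithmetic mean is the
conventional regional summary and the choice is inert on near-uniform
meshes. The hippocampus contributes two volumetric features
(`hippocampalFeatures()`): its segmented volume normalized by intracranial
volume, and its mean uptake after dividing the DVR image by the smoothed
wPVE inside the mask (same `epsilon` floor). `volumetricFeatures()`
provides the voxel-space analogue of the surface features (regional GM
volumes and masked corrected uptake) used by the volume-based comparison
scheme.

# Feature schemes and selection

`assembleFeatures()` builds the subject × feature table
(`FeatureTable`, a `SummarizedExperiment`):

* **SMF** — 24 selected multimodal features: MRI (thickness / hippocampal
  volume) and FDG (csFDG / corrected hippocampal uptake) over 12 predefined
  disease-related regions (angular, inferior frontal, inferior occipital,
  medial occipital, middle temporal, parahippocampal, posterior cingulate
  gyri, precuneus, rectus, superior occipital, supramarginal gyri, and the
  hippocampus) fixed from prior knowledge, independent of any dataset.
* **SSF-MRI / SSF-FDG** — the 12 single-modality columns.
* **all** — 80 whole-brain features (39 cortical regions + hippocampus,
  both modalities).
* **volume-based** — the 24-feature voxel-space counterpart of SMF.

`selectDataDriven()` is the data-driven alternative: two-sample t tests
(pooled variance; Welch optional) per region between two groups, ranking
regions by |t| and keeping the top 12. A region carries one feature per
modality; its score is the larger |t| of the two, so a selected region
contributes both its MRI and FDG features, mirroring the 12 × 2 structure
of SMF. Ties break alphabetically for determinism. Because single-shot
selection on the full sample leaks test information into LOOCV, the
cross-validation harness refits the selection inside every training fold by
default (`selection = "refit"`); `selection = "once"` reproduces the
single-shot reading.

# PLS-LDA

With `X` the N × d feature matrix (mean-centered; optional unit-variance
autoscaling via `autoscale = TRUE`, off by default since no scaling is part
of the core method) and `y ∈ {0,1}` the class coding, `fitPls()` extracts
latent components by sequential NIPALS: `w_a ∝ X'y`, `t_a = X w_a`,
deflation `X ← X − t_a p_a'`, giving `X = T P' + E`, `y = T q + f` with
mutually orthogonal scores. With a single response each component has a
closed form, so extraction is exact and deterministic. The component count
K is chosen by PRESS (`selectComponentsPress()`): exact leave-one-out
refits of the PLS regression at every candidate count, K = argmin of the
prediction residual sum of squares, smallest count on ties. No shortcut
formula is used — N is small in this setting and the exact criterion is
unambiguous.

`fitLda()` models the latent scores as Gaussian with class means
`μ̂_g` and a pooled within-class covariance `Σ̂`; a ridge floor
(`1e-8 · trace/K` on the diagonal) is applied only when the condition
number exceeds 1e8, which protects LOOCV folds with tiny classes. Class
priors are equal by default (`"empirical"` available). Prediction assigns a
new observation to the class with the **smaller** Mahalanobis distance
`(T − μ̂_g) Σ̂⁻¹ (T − μ̂_g)'`; the continuous discriminant score is
D(class 0) − D(class 1), positive favoring class 1, and exact ties resolve
to class 0. (Printed presentations of this rule sometimes show an argmax;
minimizing the Mahalanobis distance is the standard LDA rule and the only
direction that separates the groups.)

# Validation

`loocv()` refits the entire pipeline — data-driven selection if enabled,
PRESS, PLS, LDA — on N−1 subjects and predicts the held-out subject, once
per subject. The positive class is the more impaired diagnosis of the pair
(AD in AD/NC and AD/MCI, MCI in MCI/NC); this is the convention under which
sensitivity counts impaired subjects detected. Accuracy, sensitivity and
specificity come from the pooled confusion counts; `rocFromScores()` sweeps
a threshold over the LOOCV discriminant scores and integrates AUC by the
trapezoidal rule, which equals the Mann–Whitney concordance probability
(ties count 1/2). `logisticScreen()` fits one simple logistic regression
per feature (no covariates) by IRLS, reporting the Wald coefficient /
standard error / p-value and the AU-ROC of the fitted probabilities;
perfectly separating features are flagged with a signed infinite-beta
marker rather than silently huge estimates. P-values are raw — the screen
is descriptive and no multiplicity correction is applied.

# The synthetic phantom

`generatePhantom()` builds a fully synthetic, co-registered subject with
known truth. The cortex is a spherical shell: inner and outer surfaces are
subdivided icosahedra (default 2562 vertices) at radius 60 mm and
60 mm + thickness, with 39 regions defined as direction-Voronoi cells of
near-uniform seed directions and per-region thickness/uptake set by the
spec. Geometry uses anatomical scale — 3 mm PET voxels on a 64³ grid,
60 mm cortical radius, an 18 × 10 × 8 mm half-axis hippocampal ellipsoid,
a 12 mm reference ("cerebellum") sphere of uptake 1 — so that regional
patches (~20 mm radius) are comparable to real parcels and the fixed 20 mm
surface kernel behaves as it does on real data. Tissue fractions are exact
occupancy fractions from 3× per-axis supersampling of interface voxels;
noise-free activity is `u_region` in cortical GM, `0.25 · u_region` in WM,
the set uptakes in hippocampus and reference sphere, 0 in CSF, convolved
with the 6 mm PSF Gaussian, plus additive Gaussian noise (SD 0.01 DVR
units by default). Defaults mirror the conditions the correction is meant
to handle: 2 mm (atrophic) cortex, true GM uptake 1.2.

Two deliberate design choices: the reference mask is eroded by one PSF
FWHM so the reference mean is not depressed by boundary spill (real
cerebellar segmentations are interior structures many PSF widths across);
and truth solid angles per region are computed on a fixed fine mesh so
ground truth does not depend on the surface resolution in use.

**What the phantom shows and does not show.** With 2 mm cortex and 6 mm
PSF, uncorrected sFDG underestimates true uptake by >60% while csFDG
recovers it within ~2% — the correction does real work, and the test suite
asserts exactly this. The spherical shell exercises profiles, PVE,
smoothing and regional aggregation identically to a folded cortex and
provides closed-form shell volumes as oracles, but it does not probe
errors specific to sulcal geometry (opposing banks closer than the PSF),
surface-extraction error, or misregistration; results on the phantom are
therefore a correctness check, not a clinical validation. One consequence
of the fixed 20 mm kernel at anatomical scale is worth noting: a single
region with doubled uptake is fully recovered at the patch center but its
regional mean is diluted to ~1.7× by bleed across region borders — an
inherent property of the method, not an implementation artifact.

`generateCohort()` draws multivariate Gaussian feature tables: group sizes
default to the study's 85 NC / 71 AD (163 MCI in the three-group demo),
unit variances with exchangeable correlation 0.3 (regional features are
substantially correlated in practice), and the patient group shifted
−1.5 SD on the 12 FDG features — hypometabolism-dominated signal, negative
shifts matching the direction of the per-region logistic coefficients. The
cohort generator emulates the statistical structure of the feature tables
only; it does not model site effects, covariate structure (age, sex), or
non-Gaussian tails.

# Numerical choices

* **Mesh smoothing discretization.** Cotangent-weighted Laplacian with a
  lumped (barycentric) area mass matrix; explicit time stepping with
  `t = FWHM²/(16 ln 2)` and step size 0.25× the positivity bound
  `min_i m_i / Σ_j w_ij`. The 4× margin below the stability bound keeps the
  first-order time-stepping error well under the 2% RMS tolerance against
  the dense matrix-exponential reference (`heatKernelExact()`), while the
  positivity bound itself guarantees every step is a convex combination —
  hence constants are preserved, the area-weighted integral is conserved,
  and the discrete maximum principle holds on meshes with non-negative
  cotangent weights (true of icospheres and good-quality cortical meshes).
* **Volume smoothing.** Separable Gaussian, σ = FWHM/(2√(2 ln 2)) per axis
  in mm (anisotropic voxels handled in voxel units), kernel truncated at
  4σ, zero-padded boundaries. The phantom keeps all tissue ≥ 2 PSF widths
  from the grid edge so the boundary mode is inert.
* **Trilinear sampling** maps world mm to continuous 0-based voxel indices
  through the inverse affine and refuses points outside the voxel-center
  hull — no silent extrapolation; profiles that leave the volume are an
  error naming the offending vertex.
* **Tissue-fraction overshoot.** GM+WM+CSF sums above 1+1e-6 are rescaled
  to 1 with a warning at construction (upstream estimators routinely
  overshoot slightly); negative fractions are rejected.
* **PRESS ties** break to the smallest count; **prediction ties** to class
  0; **selection ties** alphabetically. All three make reruns
  bit-reproducible.
* **Serialization.** Models round-trip through JSON at full double
  precision (predictions agree to ~1e-14 relative).

# Problem sizes used in tests

The packaged checks run at sizes chosen to exercise the method fully while
staying desk-sized: the imaging phantom at 64³ × 3 mm with 2562-vertex
surfaces; the heat-kernel comparison on a 642-vertex mesh (dense
eigendecomposition is cubic); null calibration over 100 label-permuted
cohorts of 60 subjects × 24 features; signal recovery over 10 cohorts at
the 85/71 group sizes; and 500 replicates for the null uniformity of the
logistic screen. The three-pair demo runs the full 85/163/71 cohort.

# Known limitations

* Surface extraction, inter-subject surface registration, tissue
  classification, hippocampal segmentation and PET↔MRI co-registration are
  out of scope; inputs are assumed co-registered (the phantom generates
  them so).
* Only pairwise (two-class) discrimination is implemented; no 3-way rule.
* The 0.25 WM/GM uptake ratio is a fixed modeling constant (exposed as
  `wmWeight`), not estimated per subject.
* GIFTI container I/O is not provided; surfaces and per-vertex maps use
  Wavefront OBJ and plain text, volumes NIfTI-1.
* The logistic screen's per-feature AU-ROC uses fitted probabilities; for
  a monotone link this equals the AUC of the raw feature up to direction.
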
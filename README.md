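# cortexfuse

Surface-based multimodal FDG-PET / structural-MRI feature extraction with
weighted partial-volume correction, and PLS-LDA classification of
dementia diagnostic groups (AD / MCI / NC) validated by leave-one-out
cross-validation and ROC analysis.

## Who this is for

Neuroimaging researchers who want (a) a self-contained, testable
implementation of surface-based PET partial-volume correction — mapping
uptake onto linked cortical meshes via linked-vertex intensity profiles and
dividing by a tissue-weighted response — and (b) the accompanying
regional-feature classification pipeline, exercised end-to-end on synthetic
phantoms and cohorts with known ground truth, so every stage can be
validated without access to clinical data.

## The method

**Partial volume correction on the surface.** PET resolution (~6 mm FWHM)
biases measured uptake low in thin cortex. Per subject, the package takes a
cerebellum-normalized uptake volume (DVR), GM/WM/CSF fraction volumes, and
linked inner (WM/GM) / outer (GM/CSF) cortical meshes, and computes

    wPVE   = 1·GM + 0.25·WM + 0·CSF          (CSF: no uptake; WM ≈ GM/4)
    sFDG_i  = mean of 6 samples of DVR  along inner_i → outer_i
    swPVE_i = mean of 6 samples of the 6 mm-smoothed wPVE along the same segment
    csFDG   = smooth₂₀ₘₘ(sFDG) / smooth₂₀ₘₘ(swPVE)     (mesh heat diffusion)

with samples at fractions {0, .2, .4, .6, .8, 1} of each linked-vertex
segment. Cortical thickness is the t-link metric ‖outer_i − inner_i‖.
Regional means over a 39-region cortical parcellation plus two hippocampal
features (ICV-normalized volume; mask-based corrected uptake) yield the
24 selected multimodal features (12 predefined disease-related regions ×
{MRI, FDG}).

**Classification.** For a diagnostic pair, X (N × d, mean-centered) and
y ∈ {0,1} enter NIPALS partial least squares, X = TPᵀ + E, y = Tq + f,
with the component count K selected by exact leave-one-out PRESS; linear
discriminant analysis with pooled covariance Σ̂ runs on the latent scores,
assigning a new observation to the class g minimizing
(T − μ̂_g) Σ̂⁻¹ (T − μ̂_g)ᵀ. LOOCV refits the entire pipeline per fold;
the held-out discriminant scores build the ROC curve, and a per-feature
simple logistic regression screen (IRLS, Wald inference) quantifies each
region's individual discriminative power.

See `vignettes/cortexfuse-methods.Rmd` for assumptions, parameter
defaults, numerical choices and limitations.

## Worked example

Generate a synthetic imaging subject (spherical-shell cortex, 2 mm thick,
true GM uptake 1.2, 6 mm PSF) and recover the truth through the full
surface pipeline:

```r
library(cortexfuse)

ph  <- generatePhantom(phantomSpec())            # 64^3 x 3 mm, seed 1
dvr <- dvrNormalize(ph$pet, ph$masks$cerebellum) # cerebellar mean -> 1
fs  <- buildSurfaceFeatures(ph$pair, ph$labels, dvr, ph$tissues)

mean(fs$sfdg)    # 0.422  : uncorrected surface uptake, -65% vs truth 1.2
mean(fs$csfdg)   # 1.212  : corrected (csFDG), +1.0% vs truth
range(fs$thickness)  # 2 2 : t-link thickness recovered exactly
```

The uncorrected map loses almost two thirds of the true signal to the
partial volume effect; the correction recovers it to ~1%. Classification
on a synthetic cohort at the study group sizes (85 NC / 71 AD, −1.5 SD
shifts on the 12 FDG features):

```r
co <- generateCohort(cohortSpec())
cv <- loocv(co$table)
round(100 * c(acc = cv$accuracy, sens = cv$sensitivity, spec = cv$specificity), 1)
#   acc  sens  spec
#  98.1  98.6  97.6
cv$auc           # 0.999
```

A packaged three-comparison demo (`runPipeline()`, or
`Rscript inst/cli/cortexfuse.R demo --out runs/demo`) evaluates AD/NC,
AD/MCI and MCI/NC on a graded synthetic cohort and writes metrics JSON,
ROC points and the logistic screen per comparison.

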
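# Feature extraction: hippocampal and volumetric features, table assembly,
# and data-driven region selection.

# toy tissue scene: GM slab in a 20^3 1 mm grid
toyScene <- function() {
  d <- c(20, 20, 20)
  gm <- array(0, d); gm[6:15, 6:15, 6:15] <- 1
  wm <- array(0, d); wm[6:15, 6:15, 2:5] <- 1
  csf <- 1 - gm - wm
  aff <- diag(4)
  tissues <- TissueFractions(VolumeImage(gm, aff), VolumeImage(wm, aff),
                             VolumeImage(csf, aff))
  icv <- array(0, d); icv[2:19, 2:19, 2:19] <- 1
  list(tissues = tissues, aff = aff, d = d,
       icv = BinaryMask(icv, aff))
}

test_that("hippocampal features are the ICV volume ratio and the exact-corrected uptake", {
  sc <- toyScene()
  hip <- array(0, sc$d); hip[8:11, 8:11, 8:11] <- 1   # 64 voxels
  hipMask <- BinaryMask(hip, sc$aff)
  u <- 1.4
  wpve <- gaussianSmooth(weightedPVE(sc$tissues), 6)
  dvr <- VolumeImage(u * imageData(wpve), sc$aff)     # DVR = u * smoothed wPVE
  hf <- hippocampalFeatures(dvr, sc$tissues, hipMask, sc$icv)
  expect_equal(hf$volume, 64 / sum(imageData(sc$icv)))
  expect_equal(hf$uptake, u, tolerance = 1e-9)
  empty <- BinaryMask(array(0, sc$d), sc$aff)
  expect_error(hippocampalFeatures(dvr, sc$tissues, empty, sc$icv), "empty")
})

test_that("volumetric features integrate GM fractions and masked corrected uptake", {
  sc <- toyScene()
  lab <- array(0, sc$d)
  lab[6:15, 6:15, 6:10] <- 1      # 500 GM voxels
  lab[6:15, 6:15, 11:15] <- 2     # 500 GM voxels
  labVol <- VolumeImage(lab, sc$aff)
  lex <- c(`1` = "lower", `2` = "upper", `3` = "ghost")
  u <- 1.2
  wpve <- gaussianSmooth(weightedPVE(sc$tissues), 6)
  dvr <- VolumeImage(u * imageData(wpve), sc$aff)
  expect_message(vf <- volumetricFeatures(dvr, sc$tissues, labVol, lex, sc$icv),
                 "ghost")
  icvVol <- sum(imageData(sc$icv))
  expect_equal(vf$gmVolume[["lower"]], 500 / icvVol)
  expect_equal(vf$uptake[["upper"]], u, tolerance = 1e-9)
  # half-GM voxels contribute half their volume
  sc2 <- toyScene()
  gm2 <- imageData(sc2$tissues@gm) * 0.5
  csf2 <- 1 - gm2 - imageData(sc2$tissues@wm)
  t2 <- TissueFractions(VolumeImage(gm2, sc$aff),
                        sc2$tissues@wm, VolumeImage(csf2, sc$aff))
  vf2 <- suppressMessages(volumetricFeatures(dvr, t2, labVol, lex, sc$icv))
  expect_equal(vf2$gmVolume[["lower"]], 250 / icvVol)
})

test_that("assembled tables have the scheme-defined widths and tags", {
  subs <- list(s1 = makeSubject(0), s2 = makeSubject(0.1),
               s3 = makeSubject(-0.1), s4 = makeSubject(0.05))
  dx <- c("NC", "AD", "NC", "AD")
  smf <- assembleFeatures(subs, dx, "SMF")
  expect_equal(dim(featureMatrix(smf)), c(4L, 24L))
  ssfm <- assembleFeatures(subs, dx, "SSF-MRI")
  expect_equal(ncol(featureMatrix(ssfm)), 12L)
  expect_true(all(modality(ssfm) == "MRI"))
  ssff <- assembleFeatures(subs, dx, "SSF-FDG")
  expect_true(all(modality(ssff) == "FDG"))
  allt <- assembleFeatures(subs, dx, "all")
  expect_equal(ncol(featureMatrix(allt)), 80L)
  volb <- assembleFeatures(subs, dx, "volume-based")
  expect_equal(ncol(featureMatrix(volb)), 24L)
  expect_true(all(featureSource(volb) == "volume"))
  # SMF columns are exactly the union of the two SSF column sets
  expect_setequal(colnames(featureMatrix(smf)),
                  c(colnames(featureMatrix(ssfm)), colnames(featureMatrix(ssff))))
})

test_that("assembly is permutation-equivariant and reports missing regions", {
  subs <- list(a = makeSubject(0), b = makeSubject(0.2), c = makeSubject(-0.2),
               d = makeSubject(0.4))
  dx <- c("NC", "AD", "NC", "AD")
  t1 <- assembleFeatures(subs, dx, "SMF")
  perm <- c(3, 1, 4, 2)
  t2 <- assembleFeatures(subs[perm], dx[perm], "SMF")
  expect_identical(featureMatrix(t1)[perm, ], featureMatrix(t2))
  expect_identical(diagnosis(t1)[perm], diagnosis(t2))

  broken <- subs
  broken$b$thickness <- broken$b$thickness[-1]   # drop angular gyrus
  expect_error(assembleFeatures(broken, dx, "SMF"), "b.*angular gyrus")
})

# random cohort table over all 40 regions x 2 modalities
nullTable80 <- function(n0, n1, seed, shiftRegion = NULL, shift = 0) {
  set.seed(seed)
  feats <- smfFeatureNames(allRegions())
  X <- matrix(rnorm((n0 + n1) * 80), n0 + n1, 80, dimnames = list(NULL, feats))
  if (!is.null(shiftRegion)) {
    j <- grep(paste0(": ", shiftRegion, "$"), feats)
    X[(n0 + 1):(n0 + n1), j] <- X[(n0 + 1):(n0 + n1), j] + shift
  }
  FeatureTable(X, diagnosis = rep(c("NC", "AD"), c(n0, n1)),
               modality = sub(":.*", "", feats), source = rep("surface", 80),
               region = sub("^(MRI|FDG): ", "", feats))
}

test_that("data-driven selection finds a strongly shifted region first", {
  hits <- 0
  for (s in 1:20) {
    tab <- nullTable80(30, 30, seed = s, shiftRegion = "precuneus", shift = 2)
    sel <- selectDataDriven(tab, "AD", "NC", k = 12)
    hits <- hits + (sel[1] == "precuneus")
  }
  expect_equal(hits, 20)
  # boundary: k equal to the region count returns everything
  tab <- nullTable80(10, 10, seed = 99)
  expect_setequal(selectDataDriven(tab, "AD", "NC", k = 40), allRegions())
  expect_error(selectDataDriven(tab, "AD", "NC", k = 41), "exceeds")
})

test_that("selection is exchangeable across regions under the null", {
  counts <- stats::setNames(rep(0, 40), allRegions())
  for (s in 1:200) {
    sel <- selectDataDriven(nullTable80(20, 20, seed = 1000 + s), "AD", "NC", k = 12)
    counts[sel] <- counts[sel] + 1
  }
  # membership in the top 12 should be uniform over the 40 regions
  gof <- stats::chisq.test(counts, p = rep(1 / 40, 40))
  expect_gt(gof$p.value, 0.01)
})

test_that("selection is invariant to affine rescaling of a feature column", {
  tab <- nullTable80(25, 25, seed = 7, shiftRegion = "cuneus", shift = 1.2)
  sel1 <- selectDataDriven(tab, "AD", "NC", k = 12)
  X <- featureMatrix(tab)
  X[, 5] <- X[, 5] * 1000 + 77
  tab2 <- FeatureTable(X, diagnosis = diagnosis(tab), modality = modality(tab),
                       source = featureSource(tab),
                       region = as.character(SummarizedExperiment::rowData(tab)$region))
  expect_identical(sel1, selectDataDriven(tab2, "AD", "NC", k = 12))
})

test_that("Welch and pooled t options both run and agree on balanced clean data", {
  tab <- nullTable80(30, 30, seed = 11, shiftRegion = "insula", shift = 3)
  expect_equal(selectDataDriven(tab, "AD", "NC", k = 1),
               selectDataDriven(tab, "AD", "NC", k = 1, welch = TRUE))
})
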
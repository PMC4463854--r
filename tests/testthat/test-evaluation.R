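# LOOCV harness, confusion metrics, ROC construction, logistic screen.

test_that("confusion metrics follow their definitions and report NA when undefined", {
  truth <- c(rep("AD", 71), rep("NC", 85))
  pred <- c(rep("AD", 64), rep("NC", 7), rep("AD", 3), rep("NC", 82))
  cm <- confusionMetrics(pred, truth, "AD")
  expect_equal(cm$sensitivity, 64 / 71)
  expect_equal(cm$specificity, 82 / 85)
  expect_equal(cm$accuracy, 146 / 156)
  expect_equal(round(100 * cm$sensitivity, 1), 90.1)
  expect_equal(round(100 * cm$specificity, 1), 96.5)
  expect_equal(round(100 * cm$accuracy, 1), 93.6)

  allright <- confusionMetrics(truth, truth, "AD")
  expect_equal(c(allright$accuracy, allright$sensitivity, allright$specificity),
               c(1, 1, 1))
  allpos <- confusionMetrics(rep("AD", 156), truth, "AD")
  expect_equal(allpos$sensitivity, 1)
  expect_equal(allpos$specificity, 0)
  nopos <- confusionMetrics(rep("NC", 5), rep("NC", 5), "AD")
  expect_true(is.na(nopos$sensitivity))
  expect_equal(nopos$specificity, 1)
})

test_that("swapping the positive class swaps sensitivity and specificity", {
  set.seed(1)
  truth <- sample(c("AD", "NC"), 40, replace = TRUE)
  pred <- sample(c("AD", "NC"), 40, replace = TRUE)
  a <- confusionMetrics(pred, truth, "AD")
  b <- confusionMetrics(pred, truth, "NC")
  expect_equal(a$sensitivity, b$specificity)
  expect_equal(a$specificity, b$sensitivity)
})

test_that("the positive class is the more impaired diagnosis", {
  expect_equal(positiveClassOf(c("AD", "NC")), "AD")
  expect_equal(positiveClassOf(c("MCI", "AD")), "AD")
  expect_equal(positiveClassOf(c("NC", "MCI")), "MCI")
})

test_that("ROC handles perfect, partial and inverted rankings", {
  expect_equal(rocFromScores(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0), 1)$auc, 1)
  r <- rocFromScores(c(0.9, 0.3, 0.8, 0.2), c(1, 1, 0, 0), 1)
  expect_equal(r$auc, 0.75)
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))
  inv <- rocFromScores(c(0.9, 0.3, 0.8, 0.2), c(0, 0, 1, 1), 1)
  expect_equal(inv$auc, 1 - 0.75)
  expect_warning(cst <- rocFromScores(rep(1, 6), rep(c(0, 1), 3), 1), "constant")
  expect_equal(cst$auc, 0.5)
})

test_that("AUC equals the pairwise concordance probability", {
  set.seed(2)
  for (rep_ in 1:3) {
    scores <- round(rnorm(50), 1)          # ties included
    truth <- rbinom(50, 1, 0.4)
    if (length(unique(truth)) < 2) next
    auc <- rocFromScores(scores, truth, 1)$auc
    pos <- scores[truth == 1]; neg <- scores[truth == 0]
    conc <- 0
    for (p in pos) for (q in neg)
      conc <- conc + (p > q) + 0.5 * (p == q)
    expect_equal(auc, conc / (length(pos) * length(neg)), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an external ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(3)
  scores <- rnorm(60)
  truth <- rbinom(60, 1, 0.5)
  auc <- rocFromScores(scores, truth, 1)$auc
  ref <- suppressMessages(as.numeric(pROC::auc(truth, scores,
                                               direction = "<", quiet = TRUE)))
  expect_equal(auc, ref, tolerance = 1e-12)
})

test_that("LOOCV predicts every subject exactly once and nails separable data", {
  tab <- gaussianTable(n0 = 10, n1 = 10, d = 2, delta = 10, seed = 4)
  cv <- loocv(tab)
  expect_equal(nrow(cv$predictions), 20)
  expect_equal(sort(cv$predictions$subject), sort(rownames(featureMatrix(tab))))
  expect_equal(cv$accuracy, 1)
  expect_equal(cv$sensitivity, 1)
  expect_equal(cv$specificity, 1)
  expect_equal(cv$positiveClass, "AD")
  expect_equal(cv$auc, 1)
})

test_that("LOOCV is bit-reproducible and aborts when a fold loses a class", {
  tab <- gaussianTable(n0 = 8, n1 = 8, d = 3, delta = 2, seed = 5)
  cv1 <- loocv(tab)
  cv2 <- loocv(tab)
  expect_identical(cv1$predictions$score, cv2$predictions$score)
  tiny <- gaussianTable(n0 = 2, n1 = 8, d = 2, delta = 2, seed = 6)
  expect_error(loocv(tiny), "at least 2")
})

test_that("data-driven selection can be refitted inside each fold", {
  tab <- gaussianTable(n0 = 12, n1 = 12, d = 6, delta = 6, seed = 7)
  cv <- loocv(tab, selection = "refit", k = 2)
  expect_gte(cv$accuracy, 0.9)
  cvo <- loocv(tab, selection = "once", k = 2)
  expect_gte(cvo$accuracy, 0.9)
})

test_that("logistic regression matches the 2x2 closed form", {
  # exposed-case 10, exposed-control 5, unexposed-case 5, unexposed-control 10
  x <- c(rep(1, 15), rep(0, 15))
  y <- c(rep(1, 10), rep(0, 5), rep(1, 5), rep(0, 10))
  fit <- logisticFit(matrix(x), y)
  expect_equal(unname(fit$beta[2]), log(4), tolerance = 1e-8)
  expect_equal(unname(fit$se[2]), sqrt(1 / 10 + 1 / 5 + 1 / 5 + 1 / 10),
               tolerance = 1e-8)
  expect_false(fit$separated)
})

test_that("logistic IRLS agrees with glm on continuous data", {
  set.seed(8)
  x <- rnorm(80)
  y <- rbinom(80, 1, stats::plogis(0.5 + 0.8 * x))
  fit <- logisticFit(matrix(x), y)
  ref <- stats::glm(y ~ x, family = stats::binomial())
  expect_equal(unname(fit$beta), unname(stats::coef(ref)), tolerance = 1e-7)
  expect_equal(unname(fit$se), unname(sqrt(diag(stats::vcov(ref)))),
               tolerance = 1e-5)
})

test_that("perfect separation is flagged, not reported as huge numbers", {
  tab <- gaussianTable(n0 = 10, n1 = 10, d = 2, delta = 50, seed = 9)
  scr <- logisticScreen(tab)
  expect_true(scr$separated[1])
  expect_true(is.infinite(scr$beta[1]))
  expect_true(is.na(scr$se[1]))
})

test_that("screen betas carry the sign of the group mean difference", {
  for (s in 1:5) {
    tab <- gaussianTable(n0 = 30, n1 = 30, d = 3, delta = 0.8, seed = 20 + s)
    scr <- logisticScreen(tab)
    X <- featureMatrix(tab)
    dx <- diagnosis(tab)
    for (j in which(!scr$separated)) {
      dmean <- mean(X[dx == "AD", j]) - mean(X[dx == "NC", j])
      expect_equal(sign(scr$beta[j]), sign(dmean))
    }
  }
})

test_that("screen output carries region, modality and per-feature AUC", {
  tab <- gaussianTable(n0 = 15, n1 = 15, d = 4, delta = 1.5, seed = 30)
  scr <- logisticScreen(tab)
  expect_equal(nrow(scr), 4)
  expect_true(all(scr$modality == "FDG"))
  expect_true(all(scr$auc >= 0 & scr$auc <= 1))
  expect_gt(scr$auc[1], 0.7)   # the shifted feature discriminates
})
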
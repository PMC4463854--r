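# PLS latent extraction, PRESS component selection, pooled-covariance LDA,
# and the composed classifier.

test_that("single-column PLS reproduces simple least squares", {
  set.seed(1)
  x <- matrix(rnorm(30), 30, 1)
  y <- as.numeric(x > 0)            # 0/1 coding, perfectly monotone in x
  fit <- fitPls(x, y, 1)
  ols <- stats::lm.fit(cbind(1, x), y)$coefficients
  pred <- plsPredict(fit, x)
  expect_lt(max(abs(pred - (ols[1] + ols[2] * x[, 1]))), 1e-9)
})

test_that("full-rank PLS equals ordinary least squares and scores are orthogonal", {
  set.seed(2)
  X <- matrix(rnorm(40 * 5), 40, 5)
  y <- rbinom(40, 1, 0.5)
  fit <- fitPls(X, y, 5)
  ols <- stats::lm.fit(cbind(1, X), y)
  expect_lt(max(abs(plsPredict(fit, X) - ols$fitted.values)), 1e-6)
  G <- crossprod(fit@scores)
  offdiag <- abs(G[upper.tri(G)]) / sqrt(diag(G)[row(G)[upper.tri(G)]] *
                                         diag(G)[col(G)[upper.tri(G)]])
  expect_lt(max(offdiag), 1e-8)
})

test_that("rank-1 predictors leave nothing for a second component", {
  set.seed(3)
  base <- rnorm(25)
  X <- outer(base, c(1, 2, -1))          # rank 1
  y <- as.numeric(base > 0)
  expect_warning(fit <- fitPls(X, y, 3), "truncated")
  expect_equal(fit@A, 1L)
  # residual X after deflating component 1 carries < 1e-10 of the covariance
  Xc <- sweep(X, 2, fit@xMeans)
  E <- Xc - fit@scores %*% t(fit@loadings)
  expect_lt(sum(abs(crossprod(E, y - fit@yMean))), 1e-10 * sum(abs(crossprod(Xc, y - fit@yMean))) + 1e-12)
})

test_that("duplicating a feature column leaves full-rank fitted responses unchanged", {
  # the duplicate adds no column space, so at the numerical rank the
  # regression fit (the least-squares limit) is unchanged
  set.seed(4)
  X <- matrix(rnorm(30 * 4), 30, 4)
  y <- rbinom(30, 1, 0.5)
  f1 <- fitPls(X, y, 4)
  f2 <- suppressWarnings(fitPls(cbind(X, X[, 2]), y, 5))
  expect_lt(max(abs(plsPredict(f1, X) - plsPredict(f2, cbind(X, X[, 2])))), 1e-8)
})

test_that("PRESS selects one component for a noiseless rank-1 relation", {
  set.seed(5)
  X <- matrix(rnorm(40 * 6), 40, 6)
  w <- rnorm(6)
  y <- as.numeric(X %*% w > 0)
  # construct a noiseless linear response in a rank-1 X
  base <- rnorm(40)
  X1 <- outer(base, c(2, -1, 0.5, 1, 0, 3))
  y1 <- as.numeric(base > median(base))
  expect_equal(selectComponentsPress(X1, y1, 4)$K, 1L)
  expect_equal(selectComponentsPress(X, y, 1)$K, 1L)   # aMax = 1 boundary
})

test_that("PRESS penalizes overfit components under the null", {
  k <- integer(120)
  for (s in seq_along(k)) {
    set.seed(s)
    Xn <- matrix(rnorm(60 * 5), 60, 5)
    yn <- rbinom(60, 1, 0.5)
    if (min(table(yn)) < 2) next
    k[s] <- selectComponentsPress(Xn, yn, 5)$K
  }
  k <- k[k > 0]
  expect_gt(mean(k == 1), 0.5)                      # K = 1 the clear majority
  expect_equal(as.integer(names(which.max(table(k)))), 1L)  # and the mode
})

test_that("LDA estimates match hand arithmetic and the pooled-covariance loop", {
  T1 <- matrix(c(-1.1, -0.9, 0.9, 1.1), 4, 1)
  y <- c(0, 0, 1, 1)
  m <- fitLda(T1, y)
  expect_equal(as.numeric(m@means), c(-1, 1))
  expect_equal(as.numeric(m@pooledCov), 0.02, tolerance = 1e-12)

  set.seed(6)
  T2 <- matrix(rnorm(60 * 2), 60, 2)
  y2 <- rep(c(0, 1), 30)
  m2 <- fitLda(T2, y2)
  mu0 <- colMeans(T2[y2 == 0, ]); mu1 <- colMeans(T2[y2 == 1, ])
  S <- matrix(0, 2, 2)
  for (i in 1:60) {
    c_ <- T2[i, ] - (if (y2[i] == 0) mu0 else mu1)
    S <- S + tcrossprod(c_)
  }
  S <- S / 58
  expect_lt(max(abs(m2@pooledCov - S)), 1e-12)
})

# minimal classifier with an identity 1-D latent space
identityModel <- function(mu0, mu1, s2 = 1) {
  pls <- new("PlsModel", xMeans = 0, yMean = 0.5,
             weights = matrix(1), loadings = matrix(1), yLoadings = 1,
             innerCoef = 1, scores = matrix(c(mu0, mu1), 2, 1),
             projection = matrix(1), A = 1L)
  lda <- new("LdaModel", means = matrix(c(mu0, mu1), 2, 1),
             pooledCov = matrix(s2), priors = c(0.5, 0.5))
  new("PlsLdaModel", pls = pls, lda = lda, K = 1L,
      classLabels = c("neg", "pos"), scale = numeric(0))
}

test_that("prediction assigns the nearer class mean, ties to class 0", {
  m <- identityModel(-1, 1)
  p <- predict(m, matrix(0.2))
  expect_equal(p$class, 1L)
  expect_gt(p$score, 0)
  expect_equal(predict(m, matrix(-1))$class, 0L)   # exactly at a class mean
  expect_equal(predict(m, matrix(1))$class, 1L)
  expect_equal(predict(m, matrix(0))$class, 0L)    # equidistant tie
})

test_that("identical classes degenerate to the documented tie-break", {
  set.seed(7)
  T_ <- matrix(rep(rnorm(10), 2), 20, 1)
  y <- rep(c(0, 1), each = 10)
  T_[11:20, 1] <- T_[1:10, 1]
  m <- fitLda(T_, y)
  expect_equal(m@means[1, ], m@means[2, ])
})

test_that("well-separated Gaussians are classified near the Bayes rate", {
  set.seed(8)
  n <- 150
  Xtr <- rbind(matrix(rnorm(n * 2), n, 2),
               sweep(matrix(rnorm(n * 2), n, 2), 2, c(6, 0), "+"))
  ytr <- rep(c(0, 1), each = n)
  fit <- fitPlsLda(Xtr, ytr)
  Xte <- rbind(matrix(rnorm(1000), 500, 2),
               sweep(matrix(rnorm(1000), 500, 2), 2, c(6, 0), "+"))
  yte <- rep(c(0, 1), each = 500)
  acc <- mean(predict(fit, Xte)$class == yte)
  expect_gte(acc, 0.99)   # Bayes bound Phi(3) ~ 0.9987
})

test_that("the composed classifier separates separable data and is deterministic", {
  set.seed(9)
  X <- rbind(matrix(rnorm(20 * 3), 20, 3),
             sweep(matrix(rnorm(20 * 3), 20, 3), 2, c(8, 8, 0), "+"))
  y <- rep(c(0, 1), each = 20)
  fit <- fitPlsLda(X, y)
  expect_equal(mean(predict(fit, X)$class == y), 1)
  fit2 <- fitPlsLda(X, y)
  expect_identical(fit@pls@projection, fit2@pls@projection)
  expect_identical(predict(fit, X)$score, predict(fit2, X)$score)
})

test_that("label-permuted training accuracy stays bounded below 1", {
  accs <- numeric(40)
  for (s in seq_along(accs)) {
    set.seed(100 + s)
    X <- matrix(rnorm(60 * 5), 60, 5)
    y <- sample(rep(0:1, 30))
    fit <- fitPlsLda(X, y, aMax = 2)
    accs[s] <- mean(predict(fit, X)$class == y)
  }
  expect_lt(max(accs), 1)
  expect_gt(mean(accs), 0.45)
  expect_lt(mean(accs), 0.85)
})

test_that("autoscaled pipeline is invariant to rescaling a single feature", {
  set.seed(10)
  X <- rbind(matrix(rnorm(25 * 4), 25, 4),
             sweep(matrix(rnorm(25 * 4), 25, 4), 2, rep(1.5, 4), "+"))
  y <- rep(c(0, 1), each = 25)
  f1 <- fitPlsLda(X, y, autoscale = TRUE)
  X2 <- X; X2[, 3] <- X2[, 3] * 1e3
  f2 <- fitPlsLda(X2, y, autoscale = TRUE)
  Xn <- matrix(rnorm(40), 10, 4)
  Xn2 <- Xn; Xn2[, 3] <- Xn2[, 3] * 1e3
  expect_equal(predict(f1, Xn)$class, predict(f2, Xn2)$class)
  expect_equal(predict(f1, Xn)$score, predict(f2, Xn2)$score, tolerance = 1e-6)
})

test_that("the decision is invariant under invertible maps of the latent space", {
  set.seed(11)
  X <- rbind(matrix(rnorm(30 * 4), 30, 4),
             sweep(matrix(rnorm(30 * 4), 30, 4), 2, c(2, 1, 0, 0), "+"))
  y <- rep(c(0, 1), each = 30)
  fit <- fitPlsLda(X, y, aMax = 2)
  K <- fit@K
  A <- matrix(c(2, 0.5, -1, 1.5), 2, 2)[seq_len(K), seq_len(K), drop = FALSE]
  tfit <- fit
  tfit@pls@projection <- fit@pls@projection %*% t(A)
  tfit@lda@means <- fit@lda@means %*% t(A)
  tfit@lda@pooledCov <- A %*% fit@lda@pooledCov %*% t(A)
  Xn <- matrix(rnorm(80), 20, 4)
  expect_equal(predict(fit, Xn)$class, predict(tfit, Xn)$class)
  expect_equal(predict(fit, Xn)$score, predict(tfit, Xn)$score, tolerance = 1e-8)
})

test_that("PLS predictions agree with an independent reference implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(12)
  X <- matrix(rnorm(30 * 6), 30, 6)
  colnames(X) <- paste0("V", 1:6)
  y <- rbinom(30, 1, 0.5)
  fit <- fitPls(X, y, 3)
  ref <- mixOmics::pls(X, y, ncomp = 3, mode = "regression", scale = FALSE)
  refPred <- predict(ref, X)$predict[, , 3]
  expect_lt(max(abs(plsPredict(fit, X) - refPred)), 1e-10)
})

test_that("models survive a JSON round trip bit-for-bit in predictions", {
  set.seed(13)
  X <- rbind(matrix(rnorm(20 * 3), 20, 3),
             sweep(matrix(rnorm(20 * 3), 20, 3), 2, rep(2, 3), "+"))
  y <- rep(c(0, 1), each = 20)
  fit <- fitPlsLda(X, y, autoscale = TRUE)
  path <- tempfile(fileext = ".json")
  writePlsLdaModel(fit, path)
  back <- readPlsLdaModel(path)
  Xn <- matrix(rnorm(30), 10, 3)
  expect_equal(predict(fit, Xn)$score, predict(back, Xn)$score,
               tolerance = 1e-12)
  expect_identical(back@K, fit@K)
  expect_equal(back@pls@projection, fit@pls@projection, tolerance = 1e-14)
})

test_that("degenerate inputs raise informative errors", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(fitPls(X, rep(1, 10), 1), "both classes")
  expect_error(fitPls(X, rep(c(0, 1), 5), 5), "A must lie")
  expect_error(fitLda(matrix(rnorm(4), 4, 1), c(0, 1, 1, 1)), "at least 2")
})
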
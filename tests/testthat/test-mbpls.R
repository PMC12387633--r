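test_that("PCA matches an eigendecomposition oracle and basic identities", {
  set.seed(2)
  X <- matrix(rnorm(9), 3, 3)
  Xc <- sweep(X, 2, colMeans(X))
  pca <- fitPCA(X, ncomp = 2)
  ev <- eigen(crossprod(Xc))
  for (a in 1:2) {
    v <- ev$vectors[, a]
    if (v[which.max(abs(v))] < 0) v <- -v   # same sign convention
    expect_equal(unname(pca$loadings[, a]), v, tolerance = 1e-10)
  }
  expect_true(all(diff(pca$explained) <= 1e-12))
  # rank-1 matrix: one component carries all variance
  R1 <- outer(1:6, c(2, -1, 3)) + 5
  expect_equal(fitPCA(R1, 1)$explained, 1, tolerance = 1e-12)
  # variable permutation leaves scores unchanged up to sign
  set.seed(3)
  M <- matrix(rnorm(80), 10, 8)
  perm <- sample(8)
  s1 <- fitPCA(M, 3)$scores
  s2 <- fitPCA(M[, perm], 3)$scores
  for (a in 1:3)
    expect_equal(abs(s1[, a]), abs(s2[, a]), tolerance = 1e-10)
  expect_error(fitPCA(R1, 5), "rank")
})

test_that("PLS recovers exact linear responses and the closed-form first weight", {
  set.seed(4)
  # orthonormal centered predictors: the first weight is exactly B
  X <- qr.Q(qr(scale(matrix(rnorm(60), 12, 5), scale = FALSE)))
  B <- c(1, -2, 0.5, 0, 1)
  y <- drop(X %*% B)
  m <- fitPLS(X, cbind(y = y), ncomp = 1)
  # a noiseless linear response of orthonormal X is exact in one component
  expect_gte(m@r2yCum[1], 0.999)
  # single-column Y: first weight vector proportional to X'y
  w1 <- m@blockWeights[[1]][, 1]
  ref <- drop(crossprod(X, y - mean(y)))
  ref <- ref / sqrt(sum(ref^2))
  if (sign(ref[which.max(abs(ref))]) != sign(w1[which.max(abs(w1))])) ref <- -ref
  expect_equal(unname(w1), unname(ref), tolerance = 1e-8)
})

test_that("single-block MBPLS equals an independent NIPALS PLS2 oracle", {
  set.seed(7)
  for (k in 1:5) {
    X <- scale(matrix(rnorm(10 * 6), 10, 6))
    Y <- matrix(0, 10, 3)
    Y[cbind(1:10, sample(1:3, 10, TRUE))] <- 1
    if (any(colSums(Y) == 0)) next
    eng <- mbplsEngine(list(X), Y, ncomp = 3)
    ora <- oracleNipalsPLS(X, Y, ncomp = 3)
    for (a in 1:3) {
      s <- sign(sum(eng$superScores[, a] * ora$scores[, a]))
      expect_equal(eng$superScores[, a], s * ora$scores[, a],
                   tolerance = 1e-8, ignore_attr = TRUE)
      expect_equal(eng$blockWeights[[1]][, a], s * ora$weights[, a],
                   tolerance = 1e-8, ignore_attr = TRUE)
    }
  }
})

test_that("super scores are orthogonal, weights unit norm, R2Y monotone", {
  st <- generateStudy(smallConfig(6))
  pp <- preprocessStudy(st$blocks)
  m <- fitMBPLS(pp$blocks, st$design, ncomp = 4)
  G <- crossprod(m@superScores)
  expect_true(all(abs(G[upper.tri(G)]) <= 1e-8))
  for (b in seq_along(m@blockWeights))
    expect_equal(unname(colSums(m@blockWeights[[b]]^2)), rep(1, 4),
                 tolerance = 1e-10)
  expect_equal(unname(colSums(m@superWeights^2)), rep(1, 4), tolerance = 1e-10)
  expect_true(all(diff(m@r2yCum) >= -1e-10))
  expect_true(all(m@blockR2 >= -1e-10 & m@blockR2 <= 1 + 1e-10))
  # refit is bit-stable under the sign convention
  m2 <- fitMBPLS(pp$blocks, st$design, ncomp = 4)
  expect_identical(m@superScores, m2@superScores)
  expect_identical(m@blockWeights, m2@blockWeights)
})

test_that("permuting variables within a block permutes weights, not scores", {
  set.seed(11)
  X1 <- scale(matrix(rnorm(60), 10, 6))
  X2 <- scale(matrix(rnorm(40), 10, 4))
  Y <- matrix(0, 10, 2); Y[cbind(1:10, rep(1:2, 5))] <- 1
  perm <- sample(6)
  e1 <- mbplsEngine(list(A = X1, B = X2), Y, ncomp = 2)
  e2 <- mbplsEngine(list(A = X1[, perm], B = X2), Y, ncomp = 2)
  for (a in 1:2) {
    s <- sign(sum(e1$superScores[, a] * e2$superScores[, a]))
    expect_equal(e1$superScores[, a], s * e2$superScores[, a],
                 tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(e1$blockWeights$A[perm, a], s * e2$blockWeights$A[, a],
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("an informative block outranks a noise block on component 1", {
  set.seed(13)
  n <- 16
  grp <- rep(c(0, 1), each = n / 2)
  X1 <- scale(matrix(rnorm(n * 8), n, 8) + outer(grp, rep(2, 8)))
  X2 <- scale(matrix(rnorm(n * 8), n, 8))
  Y <- cbind(g0 = 1 - grp, g1 = grp)
  eng <- mbplsEngine(list(inf = blockScale(X1), noise = blockScale(X2)), Y, ncomp = 1)
  expect_gt(eng$blockR2["inf", 1], eng$blockR2["noise", 1])
  expect_gt(eng$superWeights[1, 1]^2, 0.5)
  # a rank-1 block aligned with the Y contrast is exhausted by component 1
  R1 <- blockScale(scale(outer(grp - mean(grp), c(1, 2, -1))))
  engR <- mbplsEngine(list(r1 = R1), Y, ncomp = 1)
  expect_equal(unname(engR$blockR2["r1", 1]), 1, tolerance = 1e-8)
})

test_that("block R2 accounting matches direct residual computation", {
  st <- generateStudy(smallConfig(8))
  pp <- preprocessStudy(st$blocks)
  m <- fitMBPLS(pp$blocks, st$design, ncomp = 4)
  for (b in names(pp$blocks)) {
    X <- blockValues(pp$blocks[[b]])
    # residual after regressing the block on the super scores sequentially
    Xd <- X
    for (a in 1:4) {
      tt <- m@superScores[, a]
      Xd <- Xd - tt %*% t(drop(crossprod(Xd, tt)) / sum(tt^2))
    }
    expect_equal(sum(m@blockR2[b, ]), 1 - sum(Xd^2) / sum(X^2),
                 tolerance = 1e-10)
  }
})

test_that("prediction reproduces the fit on training data and handles new samples", {
  st <- generateStudy(smallConfig(10))
  pp <- preprocessStudy(st$blocks)
  m <- fitMBPLS(pp$blocks, st$design, ncomp = 4, preprocessing = pp$fits)
  pr <- predict(m, lapply(pp$blocks, blockValues))
  expect_equal(pr$scores, fittedY(m), tolerance = 1e-10, ignore_attr = TRUE)
  # an all-zero (mean) sample predicts the training Y column means
  zero <- lapply(pp$blocks, function(b) matrix(0, 1, ncol(b)))
  przero <- predict(m, zero)
  expect_equal(drop(przero$scores), m@yMeans, tolerance = 1e-12,
               ignore_attr = TRUE)
  # raw-path prediction through the stored preprocessing matches
  prRaw <- predict(m, lapply(st$blocks, blockValues), raw = TRUE)
  expect_equal(prRaw$scores, pr$scores, tolerance = 1e-10)
  expect_error(mbplsEngine(list(matrix(0, 3, 2), matrix(0, 4, 2)),
                           matrix(1, 3, 2)), "mismatch")
})
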
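test_that("upper-quarter-of-range selection follows the stated arithmetic", {
  st <- generateStudy(smallConfig(16))
  pp <- preprocessStudy(st$blocks)
  m <- fitMBPLS(pp$blocks, st$design, ncomp = 4)
  # splice a known weight vector into one small block
  w <- c(0.1, 0.4, 0.9, 1.0, rep(0.1, ncol(blockValues(pp$blocks$X2)) - 4))
  m@blockWeights$X2[, 1] <- w / sqrt(sum(w^2))
  sel <- selectDiscriminant(m, axes = 1)
  selX2 <- sel[sel$block == "X2", ]
  expect_equal(unique(selX2$threshold),
               (min(abs(w)) + 0.75 * diff(range(abs(w)))) / sqrt(sum(w^2)),
               tolerance = 1e-12)
  expect_setequal(selX2$variable, variableNames(pp$blocks$X2)[3:4])
  # negating a weight vector leaves the selected set unchanged
  m2 <- m
  m2@blockWeights$X2[, 1] <- -m@blockWeights$X2[, 1]
  sel2 <- selectDiscriminant(m2, axes = 1)
  expect_setequal(sel2$variable[sel2$block == "X2"], selX2$variable)
  # degenerate equal-magnitude weights select everything
  p3 <- ncol(blockValues(pp$blocks$X3))
  m@blockWeights$X3[, 1] <- rep(1, p3) / sqrt(p3)
  sel3 <- selectDiscriminant(m, axes = 1)
  expect_equal(sum(sel3$block == "X3"), p3)
  # alternative count rule takes the top quarter by count
  selCnt <- selectDiscriminant(m, axes = 1, rule = "top-quarter-count")
  expect_equal(sum(selCnt$block == "X1"),
               ceiling(ncol(blockValues(pp$blocks$X1)) / 4))
})

test_that("direction assignment recovers the planted 'increased in' groups", {
  st <- defaultStudy()
  pp <- preprocessStudy(st$blocks)
  m <- fitMBPLS(pp$blocks, st$design, ncomp = 4)
  sel <- selectDiscriminant(m, axes = 1, design = st$design)
  # axis 1 separates CP from all three adherent conditions
  tr <- tapply(m@superScores[, 1], conditions(st$design), mean)
  expect_true(all(sign(tr[c("CG", "CPT", "CPDMS")]) == -sign(tr[["CP"]])))
  # selected contrast-1 plants carry the correct coalition
  hits <- 0; checked <- 0
  for (b in names(st$blocks)) {
    ps <- st$truth$planted$C1[[b]]
    vn <- variableNames(st$blocks[[b]])[ps$idx]
    for (k in seq_along(vn)) {
      row <- sel[sel$block == b & sel$variable == vn[k], ]
      if (!nrow(row)) next
      checked <- checked + 1
      want <- if (ps$effect[k] > 0) "CP" else "CG/CPT/CPDMS"
      hits <- hits + (row$increased_in == want)
    }
  }
  expect_gt(checked, 5)
  expect_equal(hits, checked)
  # flipping the component's sign convention leaves the assignment unchanged
  m2 <- m
  m2@superScores[, 1] <- -m2@superScores[, 1]
  up <- assignDirection(m, st$design, axis = 1, weightSign = 1)
  upFlip <- assignDirection(m2, st$design, axis = 1, weightSign = -1)
  expect_identical(up, upFlip)
  expect_silent(assignDirection(m, st$design, axis = 1, weightSign = 1,
                                floorFrac = 0))
})

test_that("biplot coordinates preserve angles and undo block divisors", {
  st <- generateStudy(smallConfig(20))
  pp <- preprocessStudy(st$blocks)
  m <- fitMBPLS(pp$blocks, st$design, ncomp = 4, preprocessing = pp$fits)
  sel <- selectDiscriminant(m, axes = c(1, 2))
  bp <- biplotCoordinates(m, sel, axes = c(1, 2))
  for (i in seq_len(nrow(bp$variables))) {
    b <- bp$variables$block[i]; v <- bp$variables$variable[i]
    w <- m@blockWeights[[b]][v, c(1, 2)]
    cosBefore <- w[1] / sqrt(sum(w^2))
    cosAfter <- bp$variables$x[i] / sqrt(bp$variables$x[i]^2 + bp$variables$y[i]^2)
    expect_equal(cosBefore, cosAfter, tolerance = 1e-12, ignore_attr = TRUE)
  }
  # duplicate variable planted in two blocks with different divisors lands
  # at identical compensated coordinates
  mm <- m
  mm@blockWeights$X2[1, 1:2] <- c(0.3, 0.4)
  mm@blockWeights$X3[1, 1:2] <- c(0.3, 0.4) * 2
  dv <- c(X1 = 1, X2 = 6, X3 = 3, X4 = 1)
  selDup <- data.frame(axis = "T1", block = c("X2", "X3"),
                       variable = c(variableNames(pp$blocks$X2)[1],
                                    variableNames(pp$blocks$X3)[1]),
                       weight = c(0.3, 0.6), threshold = 0,
                       stringsAsFactors = FALSE)
  bp2 <- biplotCoordinates(mm, selDup, axes = c(1, 2), blockDivisors = dv)
  expect_equal(bp2$variables$x[1], bp2$variables$x[2], tolerance = 1e-12)
  expect_equal(bp2$variables$y[1], bp2$variables$y[2], tolerance = 1e-12)
  expect_error(biplotCoordinates(m, sel, axes = c(1, 2, 3)), "exactly 2")
  expect_error(biplotCoordinates(m, sel, axes = c(3, 5)), "fewer components")
})

test_that("axis-1 scores separate the planktonic condition from adherent ones", {
  st <- defaultStudy()
  pp <- preprocessStudy(st$blocks)
  m <- fitMBPLS(pp$blocks, st$design, ncomp = 4)
  sil <- silhouette1d(m@superScores[, 1], conditions(st$design) == "CP")
  expect_gt(sil, 0.5)
})

test_that("identical models give identical selections and coordinates", {
  st <- generateStudy(smallConfig(22))
  pp <- preprocessStudy(st$blocks)
  m1 <- fitMBPLS(pp$blocks, st$design, ncomp = 4)
  m2 <- fitMBPLS(pp$blocks, st$design, ncomp = 4)
  expect_identical(selectDiscriminant(m1, design = st$design),
                   selectDiscriminant(m2, design = st$design))
  expect_identical(biplotCoordinates(m1)$variables,
                   biplotCoordinates(m2)$variables)
})

test_that("spurious selections on a null study are flagged unstable", {
  st <- generateStudy(nullConfig(26))
  pp <- preprocessStudy(st$blocks)
  m <- fitMBPLS(pp$blocks, st$design, ncomp = 4)
  sel <- selectDiscriminant(m, axes = 1)
  # with no group structure the selected fraction per block stays small
  for (b in names(st$blocks)) {
    frac <- sum(sel$block == b) / ncol(blockValues(st$blocks[[b]]))
    expect_lt(frac, 0.35)
  }
  selStab <- selectionStability(st$blocks, st$design, sel, ncomp = 4)
  expect_true(all(c("sign_consistency", "stable") %in% names(selStab)))
  # most null selections flip sign somewhere across the folds
  expect_gt(mean(!selStab$stable), 0.5)
})
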
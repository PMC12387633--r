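test_that("the default study reproduces the four-condition design shape", {
  st <- defaultStudy()
  expect_length(st$design, 20L)
  expect_equal(unname(table(conditions(st$design))), rep(5L, 4L),
               ignore_attr = TRUE)
  expect_equal(groupLevels(st$design), c("CG", "CPT", "CPDMS", "CP"))
  expect_equal(unname(vapply(st$blocks, ncol, integer(1))),
               c(1049L, 26L, 42L, 8800L))
  expect_true(all(vapply(st$blocks, function(b) all(blockValues(b) >= 0),
                         logical(1))))
})

test_that("generation is bit-reproducible and responsive to the seed", {
  a <- generateStudy(smallConfig(21))
  b <- generateStudy(smallConfig(21))
  cc <- generateStudy(smallConfig(22))
  for (nm in names(a$blocks)) {
    expect_identical(blockValues(a$blocks[[nm]]), blockValues(b$blocks[[nm]]))
    expect_false(identical(blockValues(a$blocks[[nm]]),
                           blockValues(cc$blocks[[nm]])))
  }
  expect_identical(a$truth$dilution, b$truth$dilution)
})

test_that("dilution multiplies rows and rejects non-positive factors", {
  X <- matrix(1:12, 3, 4)
  expect_equal(applyDilution(X, c(1, 1, 1)), X)
  d <- applyDilution(X, c(1, 2, 1))
  expect_equal(d[2, ], X[2, ] * 2)
  expect_equal(d[c(1, 3), ], X[c(1, 3), ])
  expect_error(applyDilution(X, c(1, 0, 1)), "positive")
  # diluting then PQN-normalizing against a fixed reference undoes dilution
  set.seed(12)
  R <- matrix(rexp(40, 0.01), 4, 10)
  ref <- apply(R, 2, median)
  expect_equal(pqnNormalize(applyDilution(R, c(2, 0.5, 1, 3)), ref)$values,
               pqnNormalize(R, ref)$values, tolerance = 1e-10)
})

test_that("planted group-mean differences match configured effects within 3 SE", {
  cfg <- smallConfig(5, zeroRate = 0)
  st <- generateStudy(cfg)
  cond <- conditions(st$design)
  nUp <- sum(cond == "CP"); nDn <- sum(cond != "CP")
  se <- cfg@noiseSd * sqrt(1 / nUp + 1 / nDn)
  for (b in names(st$blocks)) {
    X <- blockValues(st$blocks[[b]]) / st$truth$dilution  # pre-dilution scale
    L <- log10(X)
    ps <- st$truth$planted$C1[[b]]
    d <- colMeans(L[cond == "CP", ps$idx, drop = FALSE]) -
      colMeans(L[cond != "CP", ps$idx, drop = FALSE])
    expect_true(all(abs(d - ps$effect * cfg@noiseSd) <= 3 * se + 0.02),
                info = b)
    # non-planted variables show no systematic shift (5 SE guard band)
    planted <- unlist(lapply(st$truth$planted, function(ct) ct[[b]]$idx))
    free <- setdiff(seq_len(ncol(L)), planted)
    if (b == "X4") {
      # skip solvent-masked bins and the spill-over neighbours of planted peaks
      free <- free[colSums(X[, free, drop = FALSE] == 0) == 0]
      free <- free[!free %in% outer(planted, -3:3, "+")]
    }
    d0 <- colMeans(L[cond == "CP", free, drop = FALSE]) -
      colMeans(L[cond != "CP", free, drop = FALSE])
    expect_true(all(abs(d0) <= 5 * se + 0.02), info = b)
  }
})

test_that("zero inflation hits the requested rate, preferentially at low intensity", {
  st <- generateStudy(smallConfig(9, zeroRate = 0.2))
  X <- blockValues(st$blocks$X1)
  rate <- mean(X == 0)
  expect_gt(rate, 0.1); expect_lt(rate, 0.3)
  # zeroed entries come from low-baseline variables more often than not
  mu <- colMeans(log10(blockValues(generateStudy(smallConfig(9, zeroRate = 0))$blocks$X1)))
  zeroFrac <- colMeans(X == 0)
  expect_lt(cor(mu, zeroFrac), 0)
  # the NMR block has no stochastic dropout: its only zeros are the
  # solvent-masked bins, identical across samples
  X4 <- blockValues(st$blocks$X4)
  zeroCols <- colSums(X4 == 0)
  expect_true(all(zeroCols %in% c(0L, nrow(X4))))
})

test_that("invalid configurations are rejected", {
  expect_error(syntheticConfig(blockDims = c(X1 = 5, X2 = 5, X3 = 5, X4 = 100),
                               plantedCounts = list(C1 = c(X1 = 4, X2 = 2, X3 = 2, X4 = 4),
                                                    C2 = c(X1 = 4, X2 = 2, X3 = 2, X4 = 4),
                                                    C3 = c(X1 = 0, X2 = 0, X3 = 0, X4 = 0))),
               "too small")
  cfg <- smallConfig(1)
  cfg@plantedSets$C2$X1$idx <- cfg@plantedSets$C1$X1$idx  # force overlap
  expect_error(validObject(cfg), "overlap")
  expect_error(syntheticConfig(dilutionRange = c(-1, 2)), "positive")
  expect_error(syntheticConfig(zeroRate = 1), "zeroRate")
})

test_that("with zero effects the cross-validated AUROC is calibrated around chance", {
  macros <- vapply(401:450, function(s) {
    st <- generateStudy(nullConfig(s))
    # structureless folds may stall the NIPALS direction in a tied subspace
    cv <- suppressWarnings(
      MBPLSmetab:::.looCrossValidate(st$blocks, st$design, ncomp = 4))
    aurocMulticlass(as.character(conditions(st$design)), cv$predicted[, , 4],
                    classes = groupLevels(st$design))$macro
  }, numeric(1))
  expect_gte(mean(macros >= 0.2 & macros <= 0.8), 0.9)
})

test_that("a study with zero effects has no cross-validated predictive power", {
  st <- generateStudy(nullConfig(14))
  q2 <- looQ2Y(st$blocks, st$design, ncomp = 4)
  expect_lte(as.numeric(q2), 0)
})
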
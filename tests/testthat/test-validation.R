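test_that("R2Y follows its definition on a hand-computed toy", {
  # 4 samples, 2 classes; single exact component
  X <- scale(matrix(c(1, 2, 3, 4, 2, 1, 4, 3), 4, 2), scale = FALSE)
  Y <- cbind(a = c(1, 1, 0, 0), b = c(0, 0, 1, 1))
  m <- fitPLS(X, Y, ncomp = 1)
  Yhat <- fittedY(m)
  byHand <- 1 - sum((Y - Yhat)^2) / sum(scale(Y, scale = FALSE)^2)
  expect_equal(r2y(m, Y), byHand, tolerance = 1e-12)
  expect_equal(r2y(m), m@r2yCum[1])
  # a perfect fit gives 1: orthonormal predictors, exact linear response
  Xo <- qr.Q(qr(X))
  Yexact <- cbind(y = drop(Xo %*% c(1, 2)))
  expect_equal(r2y(fitPLS(Xo, Yexact, ncomp = 1), Yexact), 1, tolerance = 1e-9)
})

test_that("AUROC matches hand counts, the rank oracle, and is rank-invariant", {
  # positives (0.9, 0.4), negatives (0.6, 0.1): 3 of 4 concordant pairs
  lab <- c("p", "p", "n", "n")
  sc <- cbind(p = c(0.9, 0.4, 0.6, 0.1), n = c(0.1, 0.6, 0.4, 0.9))
  res <- aurocMulticlass(lab, sc)
  expect_equal(unname(res$perClass["p"]), 0.75)
  # perfectly separated scores
  expect_equal(aurocMulticlass(c("a", "a", "b"),
                               cbind(a = c(3, 2, 1), b = c(1, 2, 3)))$macro, 1)
  # ties earn half credit
  expect_equal(unname(aurocMulticlass(c("a", "b"),
                                      cbind(a = c(1, 1), b = c(1, 1)))$perClass["a"]), 0.5)
  # monotone transforms leave the statistic unchanged
  expect_equal(aurocMulticlass(lab, exp(3 * sc))$perClass, res$perClass)
  expect_error(aurocMulticlass(c("a", "a"), cbind(a = 1:2, b = 1:2)), "absent")
  # 100 random instances against the pairwise-counting oracle
  set.seed(19)
  for (k in 1:100) {
    n <- sample(6:14, 1)
    labs <- sample(c("x", "y"), n, replace = TRUE)
    if (length(unique(labs)) < 2) next
    s <- cbind(x = round(rnorm(n), 1), y = round(rnorm(n), 1))  # ties likely
    got <- aurocMulticlass(labs, s)$perClass
    expect_equal(unname(got["x"]), oracleAUROC(labs == "x", s[, "x"]),
                 tolerance = 1e-12)
    expect_equal(unname(got["y"]), oracleAUROC(labs == "y", s[, "y"]),
                 tolerance = 1e-12)
  }
})

test_that("leave-one-out Q2Y equals an externally coded naive loop", {
  # 6-sample, 2-group toy over two raw positive blocks
  set.seed(23)
  X1 <- matrix(10^runif(6 * 5, 3, 5), 6, 5)
  X2 <- matrix(10^runif(6 * 3, 3, 5), 6, 3)
  grp <- rep(c("A", "B"), 3)
  X1[grp == "A", 1] <- X1[grp == "A", 1] * 8
  des <- StudyDesign(paste0("s", 1:6), grp)
  blocks <- list(X1 = BlockMatrix(X1, "X1"), X2 = BlockMatrix(X2, "X2"))
  got <- looQ2Y(blocks, des, ncomp = 2)

  Y <- responseMatrix(des)
  press <- 0; tss <- 0
  for (i in 1:6) {
    tr <- setdiff(1:6, i)
    p1 <- oraclePreprocess(X1[tr, , drop = FALSE], X1[i, , drop = FALSE], "X1")
    p2 <- oraclePreprocess(X2[tr, , drop = FALSE], X2[i, , drop = FALSE], "X2")
    eng <- mbplsEngine(list(p1$train, p2$train), Y[tr, ], ncomp = 2)
    yhat <- mbplsPredictEngine(eng, list(p1$apply, p2$apply))
    press <- press + sum((Y[i, ] - yhat)^2)
    tss <- tss + sum((Y[i, ] - colMeans(Y[tr, ]))^2)
  }
  expect_equal(as.numeric(got), 1 - press / tss, tolerance = 1e-10)
})

test_that("an exact group signature yields near-perfect Q2Y", {
  # three groups of four with noiseless distinct block patterns
  grp <- rep(c("A", "B", "C"), each = 4)
  pat <- rbind(A = c(5, 1, 1, 3), B = c(1, 5, 2, 1), C = c(2, 1, 5, 4))
  X <- 10^pat[grp, ]
  des <- StudyDesign(sprintf("s%02d", 1:12), grp)
  q2 <- looQ2Y(list(X1 = BlockMatrix(X, "X1")), des, ncomp = 2)
  expect_gte(as.numeric(q2), 0.99)
})

test_that("responses unrelated to the blocks are not predicted (Q2Y <= 0)", {
  set.seed(29)
  for (k in 1:8) {
    X <- matrix(10^runif(12 * 10, 3, 6), 12, 10)
    des <- StudyDesign(paste0("s", 1:12), sample(rep(c("A", "B"), 6)))
    q2 <- looQ2Y(list(X1 = BlockMatrix(X, "X1")), des, ncomp = 2)
    expect_lte(as.numeric(q2), 0)
  }
})

test_that("label shuffling destroys the predictive power of a real study", {
  st <- generateStudy(smallConfig(33))
  q2real <- looQ2Y(st$blocks, st$design, ncomp = 4)
  set.seed(34)
  shuffled <- StudyDesign(st$design@samples,
                          sample(as.character(conditions(st$design))),
                          levels = groupLevels(st$design))
  q2perm <- looQ2Y(st$blocks, shuffled, ncomp = 4)
  expect_gt(as.numeric(q2real), 0.3)
  expect_lte(as.numeric(q2perm), 0)
})

test_that("evaluateModel assembles a consistent report", {
  st <- generateStudy(smallConfig(35))
  rep <- evaluateModel(st$blocks, st$design, ncomp = 4)
  expect_s4_class(rep, "ValidationReport")
  expect_equal(rep@q2y, rep@q2yCum[4])
  expect_true(all(rep@aurocClass >= 0 & rep@aurocClass <= 1))
  expect_equal(rep@aurocMacro, mean(rep@aurocClass))
  expect_identical(rep@scheme, "leave-one-out")
  # the report agrees with the standalone metric functions
  expect_equal(as.numeric(looQ2Y(st$blocks, st$design, ncomp = 4)), rep@q2y)
  df <- as.data.frame(rep)
  expect_true(all(c("R2Y", "Q2Y", "AUROC_macro") %in% df$metric))
})
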
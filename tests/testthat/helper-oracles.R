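# Independent oracles and shared fixtures.  Oracles are deliberately coded
# from the definitions (loops, eigendecompositions) and never reuse the
# package's internals.

# reduced-size four-block study for fast tests
smallConfig <- function(seed, ...) {
  syntheticConfig(
    blockDims = c(X1 = 60, X2 = 20, X3 = 20, X4 = 300),
    plantedCounts = list(C1 = c(X1 = 8, X2 = 5, X3 = 5, X4 = 8),
                         C2 = c(X1 = 6, X2 = 3, X3 = 3, X4 = 6),
                         C3 = c(X1 = 6, X2 = 3, X3 = 3, X4 = 6)),
    seed = seed, ...)
}

# tiny null config (no planted effects) for calibration checks
nullConfig <- function(seed) {
  syntheticConfig(
    blockDims = c(X1 = 40, X2 = 12, X3 = 12, X4 = 120),
    plantedCounts = list(C1 = c(X1 = 4, X2 = 2, X3 = 2, X4 = 4),
                         C2 = c(X1 = 3, X2 = 2, X3 = 2, X4 = 3),
                         C3 = c(X1 = 3, X2 = 2, X3 = 2, X4 = 3)),
    effectSize = 0, zeroRate = 0, seed = seed)
}

# full-size default study, cached per seed (generation ~2 s)
.studyCache <- new.env(parent = emptyenv())
defaultStudy <- function(seed = 20314) {
  key <- as.character(seed)
  if (is.null(.studyCache[[key]]))
    .studyCache[[key]] <- generateStudy(syntheticConfig(seed = seed))
  .studyCache[[key]]
}

# pairwise-counting AUROC: concordant pairs + half credit for ties
oracleAUROC <- function(positive, scores) {
  pos <- scores[positive]
  neg <- scores[!positive]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# plain PLS2 NIPALS from the textbook definition, run to tight tolerance
oracleNipalsPLS <- function(X, Y, ncomp, tol = 1e-14, maxit = 1e5) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  Yc <- sweep(Y, 2, colMeans(Y))
  Tm <- matrix(0, nrow(X), ncomp)
  Wm <- matrix(0, ncol(X), ncomp)
  Qm <- matrix(0, ncol(Y), ncomp)
  Pm <- matrix(0, ncol(X), ncomp)
  for (a in seq_len(ncomp)) {
    u <- Yc[, which.max(apply(Yc, 2, var))]
    for (it in seq_len(maxit)) {
      w <- drop(t(X) %*% u); w <- w / sqrt(sum(w^2))
      tt <- drop(X %*% w)
      q <- drop(t(Yc) %*% tt) / sum(tt^2)
      uNew <- drop(Yc %*% q) / sum(q^2)
      if (sqrt(sum((uNew - u)^2)) / sqrt(sum(uNew^2)) < tol) { u <- uNew; break }
      u <- uNew
    }
    w <- drop(t(X) %*% u); w <- w / sqrt(sum(w^2))
    tt <- drop(X %*% w)
    p <- drop(t(X) %*% tt) / sum(tt^2)
    q <- drop(t(Yc) %*% tt) / sum(tt^2)
    X <- X - tt %*% t(p)
    Yc <- Yc - tt %*% t(q)
    Tm[, a] <- tt; Wm[, a] <- w; Qm[, a] <- q; Pm[, a] <- p
  }
  list(scores = Tm, weights = Wm, yLoadings = Qm, xLoadings = Pm)
}

# independent re-coding of the preprocessing chain on plain matrices
oraclePreprocess <- function(Xtrain, Xapply, id, zeroRep = 1000) {
  ref <- apply(Xtrain, 2, median)
  pqnRow <- function(row) {
    ok <- row > 0 & ref > 0
    row / median(row[ok] / ref[ok])
  }
  tr <- t(apply(Xtrain, 1, pqnRow))
  ap <- t(apply(Xapply, 1, pqnRow))
  if (id %in% c("X1", "X2", "X3")) {
    tr[tr == 0] <- zeroRep; ap[ap == 0] <- zeroRep
    tr <- log10(tr); ap <- log10(ap)
  }
  mu <- colMeans(tr)
  s <- apply(tr, 2, sd)
  div <- if (id == "X1") ifelse(s > 0, sqrt(s), 1) else ifelse(s > 0, s, 1)
  trS <- sweep(sweep(tr, 2, mu), 2, div, "/")
  apS <- sweep(sweep(ap, 2, mu), 2, div, "/")
  bd <- sqrt(sum(apply(trS, 2, var)))
  list(train = trS / bd, apply = apS / bd)
}

# mean silhouette of a binary partition on a 1-D coordinate
silhouette1d <- function(x, inGroup) {
  n <- length(x)
  sil <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(inGroup == inGroup[i]); own <- setdiff(own, i)
    oth <- which(inGroup != inGroup[i])
    a <- mean(abs(x[i] - x[own]))
    b <- mean(abs(x[i] - x[oth]))
    sil[i] <- (b - a) / max(a, b)
  }
  mean(sil)
}
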
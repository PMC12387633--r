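## NIPALS multiblock PLS with super-score deflation.
##
## Per component: block weights w_b = X_b' u (unit norm) give block scores
## t_b = X_b w_b; the block scores are combined through unit-norm super
## weights into the super score t; Y-loadings q regress Y on t and the
## Y-score u = Y q closes the loop.  At convergence both every X block and Y
## are deflated by the super score.  With a single block the construction
## reduces exactly to standard NIPALS PLS2.

.unitNorm <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("zero vector encountered in NIPALS iteration")
  v / nv
}

#' Low-level multiblock PLS fit on plain matrices
#'
#' Fits the NIPALS multiblock PLS model on already-preprocessed (centered,
#' scaled, block-scaled) matrices.  Y is column-centered internally.  Sign
#' convention: the largest-magnitude entry of each component's concatenated
#' block-weight vector is made positive, so refitting is bit-stable.
#'
#' @param Xlist list of numeric matrices sharing rows (samples).
#' @param Y response matrix (e.g. one-hot group coding), n x g.
#' @param ncomp number of components A.
#' @param tol convergence tolerance on the Y-score u (default 1e-10).
#' @param maxIter maximum NIPALS iterations per component (default 5000).
#' @return list with super scores/weights, per-block weights, scores and
#'   loadings, Y-loadings, cumulative R2Y, per-block per-component R2, the
#'   Y column means, and iteration counts.
#' @export
mbplsEngine <- function(Xlist, Y, ncomp = 4, tol = 1e-10, maxIter = 5000) {
  stopifnot(is.list(Xlist), length(Xlist) >= 1L)
  Xlist <- lapply(Xlist, as.matrix)
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (any(vapply(Xlist, nrow, integer(1)) != n))
    stop("sample mismatch across blocks and Y")
  B <- length(Xlist)
  yMeans <- colMeans(Y)
  Yc <- sweep(Y, 2, yMeans)
  ssY0 <- sum(Yc^2)
  if (ssY0 == 0) stop("Y has zero variance")
  ssX0 <- vapply(Xlist, function(X) sum(X^2), numeric(1))

  Tt <- matrix(0, n, ncomp)
  Wsuper <- matrix(0, B, ncomp)
  Wb <- lapply(Xlist, function(X) matrix(0, ncol(X), ncomp))
  Tb <- lapply(Xlist, function(X) matrix(0, n, ncomp))
  Pb <- lapply(Xlist, function(X) matrix(0, ncol(X), ncomp))
  Q <- matrix(0, ncol(Y), ncomp)
  r2yCum <- numeric(ncomp)
  blockR2 <- matrix(0, B, ncomp,
                    dimnames = list(names(Xlist) %||% paste0("block", seq_len(B)), NULL))
  iters <- integer(ncomp)

  Xd <- Xlist
  Yd <- Yc
  for (a in seq_len(ncomp)) {
    if (sum(Yd^2) <= ssY0 * 1e-24)
      stop(sprintf(paste("Y variance exhausted after %d component(s);",
                         "reduce ncomp"), a - 1L))
    # start from the Y column of maximal variance (ties: lowest index)
    vc <- apply(Yd, 2, stats::var)
    u <- Yd[, which.max(vc)]
    if (sum(u^2) == 0) u <- Yd[, 1]
    it <- 0L
    repeat {
      it <- it + 1L
      wb <- lapply(Xd, function(X) .unitNorm(crossprod(X, u)))
      tb <- mapply(function(X, w) X %*% w, Xd, wb, SIMPLIFY = FALSE)
      Ts <- do.call(cbind, tb)
      wT <- .unitNorm(crossprod(Ts, u))
      tt <- drop(Ts %*% wT)
      q <- drop(crossprod(Yd, tt)) / sum(tt^2)
      uNew <- drop(Yd %*% q) / sum(q^2)
      if (sqrt(sum((uNew - u)^2)) / sqrt(sum(uNew^2)) < tol || it >= maxIter) {
        u <- uNew
        break
      }
      u <- uNew
    }
    if (it >= maxIter)
      # near-tied candidate directions (typical of structureless data) make
      # the Y-score rotate in an eigen-subspace without settling; the capped
      # solution is a valid member of that subspace and still deterministic
      warning(sprintf(paste("NIPALS reached %d iterations for component %d",
                            "without meeting tol %.1e; using the current",
                            "solution"), maxIter, a, tol))
    # sign convention on the concatenated block weights
    wAll <- unlist(wb)
    if (wAll[which.max(abs(wAll))] < 0) {
      wb <- lapply(wb, function(w) -w)
      tb <- lapply(tb, function(t) -t)
      tt <- -tt
    }
    ssBefore <- vapply(Xd, function(X) sum(X^2), numeric(1))
    pb <- lapply(Xd, function(X) drop(crossprod(X, tt)) / sum(tt^2))
    q <- drop(crossprod(Yd, tt)) / sum(tt^2)
    Xd <- mapply(function(X, p) X - tcrossprod(tt, p), Xd, pb, SIMPLIFY = FALSE)
    Yd <- Yd - tcrossprod(tt, q)
    ssAfter <- vapply(Xd, function(X) sum(X^2), numeric(1))

    Tt[, a] <- tt
    Wsuper[, a] <- wT
    for (b in seq_len(B)) {
      Wb[[b]][, a] <- wb[[b]]
      Tb[[b]][, a] <- tb[[b]]
      Pb[[b]][, a] <- pb[[b]]
    }
    Q[, a] <- q
    r2yCum[a] <- 1 - sum(Yd^2) / ssY0
    blockR2[, a] <- (ssBefore - ssAfter) / ssX0
    iters[a] <- it
  }

  for (b in seq_len(B)) {
    rownames(Wb[[b]]) <- colnames(Xlist[[b]])
    rownames(Pb[[b]]) <- colnames(Xlist[[b]])
    rownames(Tb[[b]]) <- rownames(Xlist[[b]])
  }
  rownames(Tt) <- rownames(Xlist[[1]])
  rownames(Q) <- colnames(Y)
  names(Wb) <- names(Tb) <- names(Pb) <- names(Xlist)

  list(superScores = Tt, superWeights = Wsuper, blockWeights = Wb,
       blockScores = Tb, blockLoadings = Pb, yLoadings = Q,
       r2yCum = r2yCum, blockR2 = blockR2, yMeans = yMeans,
       iterations = iters)
}

#' Predict Y scores for new samples from an engine fit
#'
#' @param fit result of \code{\link{mbplsEngine}}.
#' @param Xlist list of new-sample matrices on the model (preprocessed)
#'   scale, same variable layout as the training blocks.
#' @param ncomp components to use (default: all).
#' @return continuous predicted Y matrix (n_new x g), on the original Y
#'   scale (training Y means added back).
#' @export
mbplsPredictEngine <- function(fit, Xlist, ncomp = ncol(fit$superScores)) {
  Xlist <- lapply(Xlist, as.matrix)
  nNew <- nrow(Xlist[[1]])
  g <- nrow(fit$yLoadings)
  Yhat <- matrix(0, nNew, g, dimnames = list(rownames(Xlist[[1]]), rownames(fit$yLoadings)))
  Xd <- Xlist
  for (a in seq_len(ncomp)) {
    tb <- mapply(function(X, W) X %*% W[, a], Xd, fit$blockWeights, SIMPLIFY = FALSE)
    tt <- drop(do.call(cbind, tb) %*% fit$superWeights[, a])
    Xd <- mapply(function(X, P) X - tcrossprod(tt, P[, a]), Xd, fit$blockLoadings,
                 SIMPLIFY = FALSE)
    Yhat <- Yhat + tcrossprod(tt, fit$yLoadings[, a])
  }
  sweep(Yhat, 2, fit$yMeans, "+")
}
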
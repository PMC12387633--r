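#' Principal component analysis of one block
#'
#' Thin wrapper around the singular value decomposition of an
#' already-preprocessed (centered, scaled) block.  Scores are orthogonal,
#' loadings orthonormal, explained variance non-increasing.
#'
#' @param X a \linkS4class{BlockMatrix} or numeric matrix (assumed centered;
#'   centering is applied if column means are non-zero).
#' @param ncomp number of components (1 <= ncomp <= rank).
#' @return list with \code{scores} (n x ncomp), \code{loadings}
#'   (p x ncomp), \code{explained} (fraction of total variance per
#'   component) and \code{sdev}.
#' @export
fitPCA <- function(X, ncomp = 2) {
  if (is(X, "BlockMatrix")) X <- blockValues(X)
  X <- as.matrix(X)
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc)
  rank <- sum(sv$d > sv$d[1] * 1e-12)
  if (ncomp < 1 || ncomp > rank)
    stop(sprintf("ncomp must lie in [1, %d] (matrix rank)", rank))
  scores <- sv$u[, seq_len(ncomp), drop = FALSE] %*%
    diag(sv$d[seq_len(ncomp)], ncomp)
  loadings <- sv$v[, seq_len(ncomp), drop = FALSE]
  # deterministic sign: largest-|loading| entry positive
  for (a in seq_len(ncomp)) {
    j <- which.max(abs(loadings[, a]))
    if (loadings[j, a] < 0) {
      loadings[, a] <- -loadings[, a]
      scores[, a] <- -scores[, a]
    }
  }
  rownames(scores) <- rownames(X)
  rownames(loadings) <- colnames(X)
  explained <- (sv$d^2 / sum(sv$d^2))[seq_len(ncomp)]
  list(scores = scores, loadings = loadings, explained = explained,
       sdev = sv$d / sqrt(max(1, nrow(X) - 1)))
}
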
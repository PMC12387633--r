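## Model quality metrics: R2Y on the fit, leave-one-out Q2Y with the entire
## preprocessing chain refit inside every fold (no held-out statistic —
## PQN reference, column means/SDs, block divisors — ever enters training),
## and one-vs-rest AUROC from the cross-validated predicted Y columns.

#' R2Y: explained fraction of response variance
#'
#' \code{1 - SS(Y - Yhat) / SS(Y centered)}.  With no \code{Y} argument the
#' model's stored cumulative R2Y at its component count is returned; with a
#' response, the fitted Yhat is reconstructed from the super scores and
#' Y-loadings and compared against it.
#'
#' @param model an \linkS4class{MBPLSModel}.
#' @param Y optional response matrix (must match the training samples).
#' @export
r2y <- function(model, Y = NULL) {
  stopifnot(is(model, "MBPLSModel"))
  if (is.null(Y)) return(model@r2yCum[model@nComponents])
  Y <- as.matrix(Y)
  Yhat <- fittedY(model)
  Yc <- sweep(Y, 2, colMeans(Y))
  if (sum(Yc^2) == 0) stop("Y has zero variance")
  1 - sum((Y - Yhat)^2) / sum(Yc^2)
}

#' Fitted response of an MBPLS model
#'
#' @param model an \linkS4class{MBPLSModel}.
#' @param ncomp components to use.
#' @return fitted Yhat on the original Y scale.
#' @export
fittedY <- function(model, ncomp = model@nComponents) {
  Tt <- model@superScores[, seq_len(ncomp), drop = FALSE]
  Q <- model@yLoadings[, seq_len(ncomp), drop = FALSE]
  sweep(tcrossprod(Tt, Q), 2, model@yMeans, "+")
}

#' One-vs-rest AUROC per class and macro average
#'
#' Rank / Mann-Whitney formulation with half credit for ties: for each
#' class, the probability that a random member outranks a random non-member
#' on that class's score column.
#'
#' @param yTrue vector of true class labels.
#' @param yScore numeric matrix of per-class scores (columns named by
#'   class, or in the order of \code{classes}).
#' @param classes class order; default the column names of \code{yScore}.
#' @return list with \code{perClass} (named numeric) and \code{macro}.
#' @examples
#' aurocMulticlass(c("a","a","b","b"),
#'   cbind(a = c(.9,.4,.6,.1), b = c(.1,.6,.4,.9)))$perClass  # a: 0.75
#' @export
aurocMulticlass <- function(yTrue, yScore, classes = colnames(yScore)) {
  yScore <- as.matrix(yScore)
  if (is.null(classes)) classes <- sort(unique(as.character(yTrue)))
  if (!all(classes %in% as.character(yTrue)))
    stop("class(es) absent from yTrue: ",
         paste(setdiff(classes, as.character(yTrue)), collapse = ", "))
  if (any(!is.finite(yScore))) stop("scores must be finite")
  perClass <- vapply(seq_along(classes), function(k) {
    pos <- as.character(yTrue) == classes[k]
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0) return(NA_real_)
    r <- rank(yScore[, k])
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, numeric(1))
  names(perClass) <- classes
  list(perClass = perClass, macro = mean(perClass))
}

## one LOO pass over the full chain; returns per-component PRESS, the
## held-out predictions at each component count, and (optionally) the
## per-fold block weight matrices for stability analysis
.looCrossValidate <- function(blocks, design, params = preprocessParams(),
                              ncomp = 4, keepWeights = FALSE,
                              tol = 1e-10, maxIter = 5000) {
  stopifnot(is(design, "StudyDesign"))
  n <- length(design)
  if (n < 3) stop("leave-one-out needs at least 3 samples")
  if (any(table(design@condition) < 2))
    stop("every group needs >= 2 samples for leave-one-out")
  raw <- lapply(blocks, function(b) if (is(b, "BlockMatrix")) blockValues(b) else as.matrix(b))
  ids <- vapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    if (is(b, "BlockMatrix")) blockId(b) else names(blocks)[i] %||% paste0("B", i)
  }, character(1))
  Y <- responseMatrix(design)
  g <- ncol(Y)
  predicted <- array(NA_real_, dim = c(n, g, ncomp),
                     dimnames = list(design@samples, colnames(Y), NULL))
  press <- numeric(ncomp)
  tss <- 0
  foldWeights <- if (keepWeights) vector("list", n) else NULL

  for (i in seq_len(n)) {
    trainIdx <- setdiff(seq_len(n), i)
    fits <- mapply(function(X, id) preprocessFit(X[trainIdx, , drop = FALSE], id, params),
                   raw, ids, SIMPLIFY = FALSE)
    Xtr <- mapply(function(fit, X) preprocessTransform(fit, X[trainIdx, , drop = FALSE]),
                  fits, raw, SIMPLIFY = FALSE)
    Xte <- mapply(function(fit, X) preprocessTransform(fit, X[i, , drop = FALSE]),
                  fits, raw, SIMPLIFY = FALSE)
    names(Xtr) <- names(Xte) <- ids
    eng <- mbplsEngine(Xtr, Y[trainIdx, , drop = FALSE], ncomp = ncomp,
                       tol = tol, maxIter = maxIter)
    # accumulate the prediction component by component
    yhat <- matrix(0, 1, g)
    Xd <- Xte
    for (a in seq_len(ncomp)) {
      tb <- mapply(function(X, W) X %*% W[, a], Xd, eng$blockWeights, SIMPLIFY = FALSE)
      tt <- drop(do.call(cbind, tb) %*% eng$superWeights[, a])
      Xd <- mapply(function(X, P) X - tcrossprod(tt, P[, a]), Xd, eng$blockLoadings,
                   SIMPLIFY = FALSE)
      yhat <- yhat + tcrossprod(tt, eng$yLoadings[, a])
      predicted[i, , a] <- yhat + eng$yMeans
      press[a] <- press[a] + sum((Y[i, ] - predicted[i, , a])^2)
    }
    tss <- tss + sum((Y[i, ] - eng$yMeans)^2)
    if (keepWeights) foldWeights[[i]] <- eng$blockWeights
  }
  list(q2yCum = 1 - press / tss, press = press, tss = tss,
       predicted = predicted, foldWeights = foldWeights, ids = ids)
}

#' Leave-one-out Q2Y
#'
#' For every left-out sample the entire chain — PQN reference, zero
#' replacement + log, column centering/scaling, block divisor, and the
#' multiblock fit — is re-estimated on the remaining samples; the held-out
#' sample is then preprocessed with the training parameters and predicted.
#' \code{Q2Y = 1 - PRESS / SS(Y centered by training means)}; negative
#' values indicate no predictive power.
#'
#' @param blocks named list of raw \linkS4class{BlockMatrix} objects (or
#'   matrices).
#' @param design a \linkS4class{StudyDesign}.
#' @param params a \code{\link{preprocessParams}} bundle.
#' @param ncomp components (the reported Q2Y is cumulative at this count).
#' @return cumulative Q2Y at \code{ncomp} components, with the
#'   per-component path in attribute \code{"q2yCum"}.
#' @export
looQ2Y <- function(blocks, design, params = preprocessParams(), ncomp = 4) {
  cv <- .looCrossValidate(blocks, design, params, ncomp)
  structure(cv$q2yCum[ncomp], q2yCum = cv$q2yCum)
}

#' Full model evaluation
#'
#' Fits the model on all samples (R2Y), runs leave-one-out cross-validation
#' (Q2Y and one-vs-rest AUROC from the held-out predicted Y columns), and
#' assembles a \linkS4class{ValidationReport}.  Works identically for a
#' single-block PLS (supply one block) and the multiblock model.
#'
#' @inheritParams looQ2Y
#' @return a \linkS4class{ValidationReport}.
#' @export
evaluateModel <- function(blocks, design, params = preprocessParams(), ncomp = 4) {
  if (is(blocks, "BlockMatrix")) blocks <- stats::setNames(list(blocks), blockId(blocks))
  pp <- preprocessStudy(blocks, params)
  model <- fitMBPLS(pp$blocks, design, ncomp = ncomp, preprocessing = pp$fits)
  cv <- .looCrossValidate(blocks, design, params, ncomp)
  yTrue <- as.character(design@condition)
  looScores <- cv$predicted[, , ncomp]
  aucCV <- aurocMulticlass(yTrue, looScores, classes = groupLevels(design))
  aucFit <- aurocMulticlass(yTrue, fittedY(model), classes = groupLevels(design))
  new("ValidationReport",
      r2y = model@r2yCum[ncomp],
      q2y = cv$q2yCum[ncomp], q2yCum = cv$q2yCum,
      aurocClass = aucCV$perClass, aurocMacro = aucCV$macro,
      aurocFittedClass = aucFit$perClass, aurocFittedMacro = aucFit$macro,
      nComponents = as.integer(ncomp),
      scheme = "leave-one-out")
}

#' Serialize a ValidationReport to JSON
#'
#' @param report a \linkS4class{ValidationReport}.
#' @param path output file.
#' @export
writeReportJSON <- function(report, path) {
  obj <- list(class = "ValidationReport",
              nComponents = report@nComponents, scheme = report@scheme,
              r2y = report@r2y, q2y = report@q2y, q2yCum = report@q2yCum,
              aurocClass = as.list(report@aurocClass),
              aurocMacro = report@aurocMacro,
              aurocFittedClass = as.list(report@aurocFittedClass),
              aurocFittedMacro = report@aurocFittedMacro)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
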
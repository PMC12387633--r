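#' Fit a multiblock PLS model
#'
#' High-level interface: takes preprocessed \linkS4class{BlockMatrix}
#' objects (block-scaled; see \code{\link{preprocessStudy}}) and a
#' \linkS4class{StudyDesign}, codes Y as one-hot group membership (all g
#' columns, centered internally), and fits the NIPALS multiblock model with
#' super-score deflation.
#'
#' @param blocks named list of block-scaled \linkS4class{BlockMatrix}
#'   objects sharing sample order, or plain matrices.
#' @param design a \linkS4class{StudyDesign} (or a response matrix Y).
#' @param ncomp number of components (default 4).
#' @param tol NIPALS convergence tolerance on the Y-score (default 1e-10).
#' @param maxIter maximum iterations per component (default 5000).
#' @param preprocessing optional list of \code{PreprocessFit} transformers
#'   to store with the model (used by \code{\link{predict}} on raw data).
#' @return an \linkS4class{MBPLSModel}.
#' @export
fitMBPLS <- function(blocks, design, ncomp = 4, tol = 1e-10, maxIter = 5000,
                     preprocessing = list()) {
  if (is(blocks, "BlockMatrix")) blocks <- list(blocks)
  Xlist <- lapply(blocks, function(b) if (is(b, "BlockMatrix")) blockValues(b) else as.matrix(b))
  ids <- vapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    if (is(b, "BlockMatrix")) blockId(b) else names(blocks)[i] %||% paste0("B", i)
  }, character(1))
  names(Xlist) <- ids
  sn <- lapply(Xlist, rownames)
  if (length(unique(vapply(sn, paste, character(1), collapse = "\r"))) > 1L)
    stop("blocks disagree on sample ids/order")
  if (is(design, "StudyDesign")) {
    if (!is.null(sn[[1]]) && !identical(sn[[1]], design@samples))
      stop("block sample order does not match the design")
    Y <- responseMatrix(design)
    groups <- groupLevels(design)
  } else {
    Y <- as.matrix(design)
    groups <- colnames(Y) %||% paste0("class", seq_len(ncol(Y)))
  }
  fit <- mbplsEngine(Xlist, Y, ncomp = ncomp, tol = tol, maxIter = maxIter)
  new("MBPLSModel", superScores = fit$superScores,
      superWeights = fit$superWeights, blockWeights = fit$blockWeights,
      blockScores = fit$blockScores, blockLoadings = fit$blockLoadings,
      yLoadings = fit$yLoadings, r2yCum = fit$r2yCum, blockR2 = fit$blockR2,
      yMeans = fit$yMeans, groups = groups, blockNames = ids,
      nComponents = as.integer(ncomp), iterations = fit$iterations,
      preprocessing = preprocessing)
}

#' Fit a single-block PLS model
#'
#' Standard NIPALS PLS2; implemented as the one-block case of the multiblock
#' construction, to which it is mathematically identical.
#'
#' @inheritParams fitMBPLS
#' @param X a \linkS4class{BlockMatrix} or matrix.
#' @return an \linkS4class{MBPLSModel} with one block.
#' @export
fitPLS <- function(X, design, ncomp = 2, tol = 1e-10, maxIter = 5000) {
  nm <- if (is(X, "BlockMatrix")) blockId(X) else "X"
  blocks <- stats::setNames(list(X), nm)
  fitMBPLS(blocks, design, ncomp = ncomp, tol = tol, maxIter = maxIter)
}

.engineFromModel <- function(model) {
  list(superScores = model@superScores, superWeights = model@superWeights,
       blockWeights = model@blockWeights, blockScores = model@blockScores,
       blockLoadings = model@blockLoadings, yLoadings = model@yLoadings,
       yMeans = model@yMeans)
}

#' Predict group scores for new samples
#'
#' New blocks must be on the model scale (preprocessed with the training
#' parameters); when the model stores preprocessing transformers and
#' \code{raw = TRUE}, raw blocks are transformed first.  The class call per
#' sample is the argmax over predicted Y columns.
#'
#' @param object an \linkS4class{MBPLSModel}.
#' @param newBlocks named list of matrices (or BlockMatrix) for new samples.
#' @param ncomp components to use (default: all fitted).
#' @param raw are the new blocks raw intensities needing the stored
#'   preprocessing transformers?
#' @param ... ignored.
#' @return list with \code{scores} (continuous predicted Y, n_new x g) and
#'   \code{class} (factor of argmax calls).
#' @export
setMethod("predict", "MBPLSModel",
  function(object, newBlocks, ncomp = object@nComponents, raw = FALSE, ...) {
    if (is(newBlocks, "BlockMatrix")) newBlocks <- list(newBlocks)
    Xlist <- lapply(newBlocks, function(b)
      if (is(b, "BlockMatrix")) blockValues(b) else as.matrix(b))
    if (is.null(names(Xlist)) && length(Xlist) == length(object@blockNames))
      names(Xlist) <- object@blockNames
    Xlist <- Xlist[object@blockNames]
    if (raw) {
      if (!length(object@preprocessing))
        stop("model stores no preprocessing transformers")
      Xlist <- mapply(function(fit, X) preprocessTransform(fit, X),
                      object@preprocessing[object@blockNames], Xlist,
                      SIMPLIFY = FALSE)
    }
    for (b in seq_along(Xlist)) {
      tr <- rownames(object@blockWeights[[b]])
      cn <- colnames(Xlist[[b]])
      if (!is.null(tr) && !is.null(cn) && !identical(tr, cn))
        stop("variable ids of block ", object@blockNames[b],
             " do not match the training layout")
    }
    scores <- mbplsPredictEngine(.engineFromModel(object), Xlist, ncomp = ncomp)
    cls <- factor(object@groups[max.col(scores, ties.method = "first")],
                  levels = object@groups)
    list(scores = scores, class = cls)
  })

#' Per-block explained variance
#'
#' Incremental fraction of each block's initial sum of squares removed by
#' each component's super-score deflation.  Reported two ways: the deflation
#' R2 (default) and the squared super weights (each component's super-weight
#' vector squared, summing to 1 over blocks).
#'
#' @param model a fitted \linkS4class{MBPLSModel}.
#' @param type \code{"deflation"} or \code{"superweight"}.
#' @return B x A matrix of per-block per-component contributions.
#' @export
blockExplainedVariance <- function(model, type = c("deflation", "superweight")) {
  stopifnot(is(model, "MBPLSModel"))
  type <- match.arg(type)
  if (type == "deflation") return(model@blockR2)
  sw <- model@superWeights^2
  dimnames(sw) <- dimnames(model@blockR2)
  sw
}

#' Cumulative R2Y of a fitted model
#'
#' @param model an \linkS4class{MBPLSModel}.
#' @param ncomp component count (default: all); returns the cumulative R2Y
#'   after that many components.
#' @export
modelR2Y <- function(model, ncomp = model@nComponents) {
  stopifnot(is(model, "MBPLSModel"))
  model@r2yCum[ncomp]
}

#' Serialize a fitted model to JSON
#'
#' Deterministic field order; numeric precision is not truncated.
#'
#' @param model an \linkS4class{MBPLSModel}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeModelJSON <- function(model, path) {
  obj <- list(
    class = "MBPLSModel",
    nComponents = model@nComponents,
    blocks = model@blockNames,
    groups = model@groups,
    deflation = "super-score",
    r2yCum = model@r2yCum,
    blockR2 = model@blockR2,
    superWeights = model@superWeights,
    superScores = model@superScores,
    blockWeights = model@blockWeights,
    blockLoadings = model@blockLoadings,
    yLoadings = model@yLoadings,
    yMeans = model@yMeans,
    iterations = model@iterations)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
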
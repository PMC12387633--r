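## Preprocessing chain for the four analytical blocks:
##   PQN -> (MS blocks only) zero replacement + log -> centering +
##   Pareto/UV column scaling -> block variance scaling.
## Every stage exists in two forms: a "fit" form that estimates parameters
## from training samples and a "transform" form that re-applies stored
## parameters, so cross-validation folds never see held-out statistics.

.colSds <- function(X) {
  n <- nrow(X)
  if (n < 2L) return(rep(0, ncol(X)))
  mu <- colMeans(X)
  sqrt(colSums((X - rep(mu, each = n))^2) / (n - 1L))
}

## ---- PQN ------------------------------------------------------------------

.pqnFactors <- function(X, reference) {
  vapply(seq_len(nrow(X)), function(i) {
    row <- X[i, ]
    ok <- row > 0 & reference > 0
    if (!any(ok))
      stop(sprintf("sample row %d has no positive overlap with the PQN reference", i))
    stats::median(row[ok] / reference[ok])
  }, numeric(1))
}

.pqnCore <- function(X, reference = NULL) {
  if (any(X < 0)) stop("PQN expects non-negative intensities")
  if (is.null(reference)) reference <- apply(X, 2, stats::median)
  stopifnot(length(reference) == ncol(X))
  f <- .pqnFactors(X, reference)
  list(values = X / f, factors = f, reference = reference)
}

#' @rdname pqnNormalize
#' @export
setMethod("pqnNormalize", "matrix", function(x, reference = NULL) {
  .pqnCore(x, reference)
})

#' @rdname pqnNormalize
#' @export
setMethod("pqnNormalize", "BlockMatrix", function(x, reference = NULL) {
  res <- .pqnCore(x@values, reference)
  x@values <- res$values
  x@params$pqnFactors <- res$factors
  x@params$pqnReference <- res$reference
  .advanceState(x, "pqn")
})

## ---- zero replacement + log -----------------------------------------------

.zeroLogCore <- function(X, zeroReplacement, logBase) {
  if (any(X < 0)) stop("negative entries cannot be log-transformed")
  stopifnot(zeroReplacement > 0, logBase > 1)
  X[X == 0] <- zeroReplacement
  log(X, base = logBase)
}

#' @rdname replaceZerosLog
#' @export
setMethod("replaceZerosLog", "matrix",
  function(x, zeroReplacement = 1000, logBase = 10) {
    .zeroLogCore(x, zeroReplacement, logBase)
  })

#' @rdname replaceZerosLog
#' @export
setMethod("replaceZerosLog", "BlockMatrix",
  function(x, zeroReplacement = 1000, logBase = 10) {
    if (x@blockId == "X4")
      stop("the NMR block (X4) is not log-transformed")
    x@values <- .zeroLogCore(x@values, zeroReplacement, logBase)
    x@params$zeroReplacement <- zeroReplacement
    x@params$logBase <- logBase
    .advanceState(x, "logged")
  })

## ---- centering + column scaling -------------------------------------------

.centerScaleFit <- function(X, method) {
  mu <- colMeans(X)
  s <- .colSds(X)
  div <- switch(method,
    uv = ifelse(s > 0, s, 1),
    pareto = ifelse(s > 0, sqrt(s), 1),
    none = rep(1, ncol(X)))
  list(colMeans = mu, colDiv = div, method = method)
}

.centerScaleApply <- function(X, fit) {
  sweep(sweep(X, 2, fit$colMeans, "-"), 2, fit$colDiv, "/")
}

#' @rdname centerScale
#' @export
setMethod("centerScale", "matrix", function(x, method = c("uv", "pareto", "none")) {
  method <- match.arg(method)
  .centerScaleApply(x, .centerScaleFit(x, method))
})

#' @rdname centerScale
#' @export
setMethod("centerScale", "BlockMatrix", function(x, method = c("uv", "pareto", "none")) {
  method <- match.arg(method)
  fit <- .centerScaleFit(x@values, method)
  x@values <- .centerScaleApply(x@values, fit)
  x@params$colMeans <- fit$colMeans
  x@params$colDiv <- fit$colDiv
  x@params$scaling <- method
  .advanceState(x, c("centered", "scaled"))
})

## ---- block variance scaling -----------------------------------------------

.blockDivisor <- function(X) {
  tv <- sum(.colSds(X)^2)
  if (tv <= 0) stop("block has zero total variance; cannot block-scale")
  sqrt(tv)
}

#' @rdname blockScale
#' @export
setMethod("blockScale", "matrix", function(x) {
  d <- .blockDivisor(x)
  x / d
})

#' @rdname blockScale
#' @export
setMethod("blockScale", "BlockMatrix", function(x) {
  if (!.hasState(x, "scaled"))
    stop("state error: block scaling requires centering/column scaling first ",
         "(block ", x@blockId, " is at state: ",
         paste(x@state, collapse = " -> "), ")")
  d <- .blockDivisor(x@values)
  x@values <- x@values / d
  x@params$blockDiv <- d
  .advanceState(x, "block_scaled")
})

## ---- dilution --------------------------------------------------------------

.dilutionCore <- function(X, factors) {
  stopifnot(length(factors) == nrow(X))
  if (any(factors <= 0)) stop("dilution factors must be positive")
  X * factors
}

#' @rdname applyDilution
#' @export
setMethod("applyDilution", "matrix", function(x, factors) .dilutionCore(x, factors))

#' @rdname applyDilution
#' @export
setMethod("applyDilution", "BlockMatrix", function(x, factors) {
  x@values <- .dilutionCore(x@values, factors)
  x
})

## ---- parameter bundles and the full chain ----------------------------------

#' Preprocessing parameter bundle
#'
#' @param zeroReplacement intensity substituted for zeros in the MS blocks
#'   before the log (default 1000).
#' @param logBase log base for the MS blocks (default 10; the base only
#'   rescales columns and is absorbed by unit-variance scaling, but matters
#'   for the Pareto-scaled block).
#' @param scaling named per-block column scaling; default Pareto for X1 and
#'   unit variance for X2, X3, X4.
#' @param logBlocks blocks that receive zero replacement + log.
#' @return a list of class \code{"PreprocessParams"}.
#' @export
preprocessParams <- function(zeroReplacement = 1000, logBase = 10,
                             scaling = c(X1 = "pareto", X2 = "uv",
                                         X3 = "uv", X4 = "uv"),
                             logBlocks = c("X1", "X2", "X3")) {
  stopifnot(zeroReplacement > 0, all(scaling %in% c("pareto", "uv", "none")))
  structure(list(zeroReplacement = zeroReplacement, logBase = logBase,
                 scaling = scaling, logBlocks = logBlocks),
            class = "PreprocessParams")
}

.blockScaling <- function(params, id) {
  if (id %in% names(params$scaling)) params$scaling[[id]] else "uv"
}

#' Fit the preprocessing chain on training samples
#'
#' Estimates every data-dependent preprocessing parameter (PQN reference,
#' column means and divisors, block divisor) from the given samples only.
#' Use \code{\link{preprocessTransform}} to apply the fitted chain to any
#' samples, including held-out ones.
#'
#' @param X raw intensity matrix (samples x variables) of one block.
#' @param id block id ("X1".."X4"); decides log transform and scaling.
#' @param params a \code{\link{preprocessParams}} bundle.
#' @return a list of class \code{"PreprocessFit"}.
#' @export
preprocessFit <- function(X, id, params = preprocessParams()) {
  ref <- apply(X, 2, stats::median)
  Xp <- .pqnCore(X, ref)$values
  doLog <- id %in% params$logBlocks
  if (doLog) Xp <- .zeroLogCore(Xp, params$zeroReplacement, params$logBase)
  csFit <- .centerScaleFit(Xp, .blockScaling(params, id))
  Xc <- .centerScaleApply(Xp, csFit)
  d <- .blockDivisor(Xc)
  structure(list(id = id, pqnReference = ref, doLog = doLog,
                 zeroReplacement = params$zeroReplacement,
                 logBase = params$logBase, centerScale = csFit,
                 blockDiv = d),
            class = "PreprocessFit")
}

#' Apply a fitted preprocessing chain
#'
#' @param fit a \code{"PreprocessFit"} from \code{\link{preprocessFit}}.
#' @param X raw intensity matrix with the training variable layout (may be
#'   a single row).
#' @return fully preprocessed matrix on the model scale.
#' @export
preprocessTransform <- function(fit, X) {
  stopifnot(inherits(fit, "PreprocessFit"))
  X <- as.matrix(X)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  Xp <- X / .pqnFactors(X, fit$pqnReference)
  if (fit$doLog) Xp <- .zeroLogCore(Xp, fit$zeroReplacement, fit$logBase)
  .centerScaleApply(Xp, fit$centerScale) / fit$blockDiv
}

#' Preprocess a full study
#'
#' Runs the complete chain (PQN, MS-block zero replacement + log, centering
#' and per-block column scaling, block variance scaling) on each block and
#' returns both the processed \linkS4class{BlockMatrix} objects and the
#' fitted transformers.
#'
#' @param blocks named list of raw \linkS4class{BlockMatrix} objects.
#' @param params a \code{\link{preprocessParams}} bundle.
#' @return list with \code{blocks} (processed BlockMatrix list) and
#'   \code{fits} (PreprocessFit list).
#' @export
preprocessStudy <- function(blocks, params = preprocessParams()) {
  stopifnot(is.list(blocks), length(blocks) >= 1L)
  fits <- list()
  out <- list()
  for (nm in names(blocks)) {
    bm <- blocks[[nm]]
    stopifnot(is(bm, "BlockMatrix"))
    fit <- preprocessFit(bm@values, bm@blockId, params)
    vals <- preprocessTransform(fit, bm@values)
    dimnames(vals) <- dimnames(bm@values)
    pb <- BlockMatrix(vals, bm@blockId,
                      state = .BLOCK_STATES,
                      params = list(pqnReference = fit$pqnReference,
                                    colMeans = fit$centerScale$colMeans,
                                    colDiv = fit$centerScale$colDiv,
                                    scaling = fit$centerScale$method,
                                    blockDiv = fit$blockDiv))
    if (!fit$doLog) pb@state <- setdiff(pb@state, "logged")
    fits[[nm]] <- fit
    out[[nm]] <- pb
  }
  list(blocks = out, fits = fits)
}
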
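## Central S4 containers.  BlockMatrix keeps samples in rows (the orientation
## of the delimited files the pipeline exchanges); preprocessing state is a
## monotone flag vector so out-of-order stages can be refused.

.BLOCK_STATES <- c("raw", "pqn", "logged", "centered", "scaled", "block_scaled")

#' BlockMatrix: one samples-by-variables intensity matrix
#'
#' Container for a single analytical block (LC-HRMS2 features, GC-MS
#' features, or binned 1H NMR spectra) of a multi-platform study.  Rows are
#' samples, columns are variables.  The \code{state} slot records which
#' preprocessing stages have been applied, and \code{params} stores the
#' fitted preprocessing parameters (PQN factors and reference, column means
#' and scale divisors, block divisor) so they can be re-applied to new
#' samples.
#'
#' @slot values numeric matrix, samples x variables, with dimnames.
#' @slot blockId single string identifying the block (e.g. "X1").
#' @slot state character vector of completed stages, a prefix-closed subset
#'   of \code{c("raw","pqn","logged","centered","scaled","block_scaled")}.
#' @slot params named list of stored preprocessing parameters.
#' @export
setClass("BlockMatrix",
  representation(values = "matrix", blockId = "character",
                 state = "character", params = "list"),
  prototype(state = "raw", params = list()))

setValidity("BlockMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v)) msg <- c(msg, "'values' must be a numeric matrix")
  if (length(object@blockId) != 1L || is.na(object@blockId) || !nzchar(object@blockId))
    msg <- c(msg, "'blockId' must be a single non-empty string")
  if (!all(object@state %in% .BLOCK_STATES))
    msg <- c(msg, sprintf("unknown state flag(s): %s",
                          paste(setdiff(object@state, .BLOCK_STATES), collapse = ", ")))
  if (is.numeric(v) && anyNA(v)) msg <- c(msg, "'values' must not contain NA")
  if (length(msg)) msg else TRUE
})

#' Construct a BlockMatrix
#'
#' @param values numeric matrix, samples x variables.
#' @param blockId block identifier, e.g. \code{"X1"}.
#' @param state completed preprocessing stages (default \code{"raw"}).
#' @param params stored preprocessing parameters.
#' @return a \linkS4class{BlockMatrix}.
#' @examples
#' bm <- BlockMatrix(matrix(1:6, 2, 3), "X2")
#' dim(bm)
#' @export
BlockMatrix <- function(values, blockId, state = "raw", params = list()) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("S%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("%s_v%d", blockId, seq_len(ncol(values)))
  new("BlockMatrix", values = values, blockId = blockId,
      state = state, params = params)
}

#' StudyDesign: sample-to-condition assignment
#'
#' @slot samples character vector of sample ids.
#' @slot condition factor of the same length giving each sample's condition;
#'   factor levels define the group order used throughout the package.
#' @export
setClass("StudyDesign",
  representation(samples = "character", condition = "factor"))

setValidity("StudyDesign", function(object) {
  msg <- character()
  if (length(object@samples) != length(object@condition))
    msg <- c(msg, "'samples' and 'condition' lengths differ")
  if (anyDuplicated(object@samples))
    msg <- c(msg, "duplicated sample ids")
  if (any(table(object@condition) < 1L))
    msg <- c(msg, "every condition level needs at least one sample")
  if (length(msg)) msg else TRUE
})

#' Construct a StudyDesign
#'
#' @param samples character sample ids.
#' @param condition condition label per sample (character or factor).
#' @param levels optional explicit group order.
#' @export
StudyDesign <- function(samples, condition, levels = NULL) {
  if (is.null(levels)) levels <- unique(as.character(condition))
  new("StudyDesign", samples = as.character(samples),
      condition = factor(as.character(condition), levels = levels))
}

#' MBPLSModel: fitted multiblock PLS model
#'
#' Holds everything the NIPALS multiblock fit produces: super scores T
#' (consensus sample coordinates), unit-norm super weights combining the
#' block scores, per-block weight matrices W (the biplot variable
#' coordinates), block scores and loadings, Y-weights/loadings, the
#' per-component per-block explained variance, and cumulative R2Y.
#'
#' @slot superScores n x A matrix of super scores.
#' @slot superWeights B x A matrix of unit-norm super weights.
#' @slot blockWeights list (per block) of p_b x A unit-norm weight matrices.
#' @slot blockScores list of n x A block score matrices.
#' @slot blockLoadings list of p_b x A loading (P) matrices.
#' @slot yLoadings g x A matrix of Y regression loadings (per component).
#' @slot r2yCum numeric(A), cumulative R2Y after each component.
#' @slot blockR2 B x A matrix of incremental explained block variance.
#' @slot yMeans numeric(g) column means used to center Y.
#' @slot groups group labels (columns of Y).
#' @slot blockNames block ids, in fitting order.
#' @slot nComponents number of components A.
#' @slot iterations NIPALS iterations used per component.
#' @slot preprocessing list of fitted preprocessing transformers (possibly
#'   empty when the model was fitted on pre-transformed matrices).
#' @export
setClass("MBPLSModel",
  representation(superScores = "matrix", superWeights = "matrix",
                 blockWeights = "list", blockScores = "list",
                 blockLoadings = "list", yLoadings = "matrix",
                 r2yCum = "numeric", blockR2 = "matrix",
                 yMeans = "numeric", groups = "character",
                 blockNames = "character", nComponents = "integer",
                 iterations = "integer", preprocessing = "list"))

setValidity("MBPLSModel", function(object) {
  A <- object@nComponents
  msg <- character()
  if (ncol(object@superScores) != A) msg <- c(msg, "superScores/nComponents mismatch")
  if (length(object@r2yCum) != A) msg <- c(msg, "r2yCum length mismatch")
  if (A > 1 && any(diff(object@r2yCum) < -1e-8))
    msg <- c(msg, "cumulative R2Y must be nondecreasing")
  if (any(object@blockR2 < -1e-8 | object@blockR2 > 1 + 1e-8))
    msg <- c(msg, "block R2 entries must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' ValidationReport: model quality metrics
#'
#' @slot r2y fraction of Y variance explained by the fitted model.
#' @slot q2y cumulative leave-one-out Q2Y at the model's component count
#'   (may be negative).
#' @slot q2yCum per-component cumulative Q2Y.
#' @slot aurocClass named one-vs-rest AUROC per class, from cross-validated
#'   predicted scores.
#' @slot aurocMacro unweighted mean of the per-class AUROCs.
#' @slot aurocFittedClass,aurocFittedMacro same metrics computed from fitted
#'   (non-cross-validated) scores, for comparison.
#' @slot nComponents components used.
#' @slot scheme cross-validation scheme descriptor.
#' @export
setClass("ValidationReport",
  representation(r2y = "numeric", q2y = "numeric", q2yCum = "numeric",
                 aurocClass = "numeric", aurocMacro = "numeric",
                 aurocFittedClass = "numeric", aurocFittedMacro = "numeric",
                 nComponents = "integer", scheme = "character"))

setValidity("ValidationReport", function(object) {
  msg <- character()
  if (object@r2y < -1e-8 || object@r2y > 1 + 1e-8)
    msg <- c(msg, "R2Y must lie in [0,1]")
  if (length(object@aurocClass) &&
      any(object@aurocClass < -1e-12 | object@aurocClass > 1 + 1e-12))
    msg <- c(msg, "AUROC values must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' SyntheticConfig: parameters of the synthetic four-block study generator
#'
#' @slot nPerGroup replicates per condition.
#' @slot groups ordered condition labels.
#' @slot blockDims named variable counts per block.
#' @slot plantedSets nested list, contrast -> block -> list(idx, effect):
#'   variable indices and signed effect sizes (multiples of the within-group
#'   SD on the log10 scale).
#' @slot dilutionRange positive interval for the per-sample multiplicative
#'   dilution factor.
#' @slot zeroRate fraction of entries set to exact 0 in the MS blocks.
#' @slot noiseSd within-group SD on the log10 scale.
#' @slot seed integer seed; per-block child seeds are derived from it.
#' @export
setClass("SyntheticConfig",
  representation(nPerGroup = "integer", groups = "character",
                 blockDims = "integer", plantedSets = "list",
                 dilutionRange = "numeric", zeroRate = "numeric",
                 noiseSd = "numeric", seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  if (object@nPerGroup < 1L) msg <- c(msg, "nPerGroup must be >= 1")
  if (any(object@blockDims < 1L)) msg <- c(msg, "all block dims must be >= 1")
  if (length(object@dilutionRange) != 2L || any(object@dilutionRange <= 0) ||
      diff(object@dilutionRange) < 0)
    msg <- c(msg, "dilutionRange must be a positive ordered interval")
  if (object@zeroRate < 0 || object@zeroRate >= 1)
    msg <- c(msg, "zeroRate must lie in [0,1)")
  if (object@noiseSd <= 0) msg <- c(msg, "noiseSd must be positive")
  for (b in names(object@blockDims)) {
    ids <- unlist(lapply(object@plantedSets, function(ct)
      if (!is.null(ct[[b]])) ct[[b]]$idx else integer()))
    if (anyDuplicated(ids))
      msg <- c(msg, sprintf("planted sets overlap across contrasts in block %s", b))
    if (length(ids) && max(ids) > object@blockDims[[b]])
      msg <- c(msg, sprintf("planted index exceeds block %s dimension", b))
  }
  if (length(msg)) msg else TRUE
})
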
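#' @import methods
NULL

#' @export
setGeneric("blockValues", function(x) standardGeneric("blockValues"))

#' @export
setGeneric("blockId", function(x) standardGeneric("blockId"))

#' @export
setGeneric("blockState", function(x) standardGeneric("blockState"))

#' @export
setGeneric("sampleNames", function(x) standardGeneric("sampleNames"))

#' @export
setGeneric("variableNames", function(x) standardGeneric("variableNames"))

#' @export
setGeneric("preprocParams", function(x) standardGeneric("preprocParams"))

#' @export
setGeneric("conditions", function(x) standardGeneric("conditions"))

#' @export
setGeneric("groupLevels", function(x) standardGeneric("groupLevels"))

#' @export
setGeneric("responseMatrix", function(x) standardGeneric("responseMatrix"))

#' Probabilistic quotient normalization
#'
#' Divides every sample row by the median of its elementwise ratios to a
#' reference spectrum, computed over entries positive in both the row and the
#' reference.  This removes per-sample dilution / total-amount effects.
#'
#' @param x a \linkS4class{BlockMatrix} or a plain numeric matrix
#'   (samples x variables) with non-negative entries.
#' @param reference optional reference spectrum (numeric vector, one value per
#'   variable).  Defaults to the per-variable median over all samples.
#' @return For a matrix: a list with elements \code{values}, \code{factors}
#'   and \code{reference}.  For a \linkS4class{BlockMatrix}: a new
#'   \code{BlockMatrix} with state \code{"pqn"} and the factors and reference
#'   stored in its parameter list.
#' @export
setGeneric("pqnNormalize", function(x, reference = NULL) standardGeneric("pqnNormalize"))

#' Zero replacement and log transform
#'
#' Replaces exact zeros by a fixed positive intensity and then applies an
#' elementwise logarithm.  Used for the MS blocks (X1--X3) only; binned NMR
#' intensities stay on their native scale.
#'
#' @param x a \linkS4class{BlockMatrix} (block id X1, X2 or X3) or matrix.
#' @param zeroReplacement intensity substituted for zeros (default 1000).
#' @param logBase base of the logarithm (default 10).
#' @export
setGeneric("replaceZerosLog", function(x, zeroReplacement = 1000, logBase = 10)
  standardGeneric("replaceZerosLog"))

#' Column centering and scaling
#'
#' Mean-centers every column, then scales by the column standard deviation
#' (\code{"uv"}), by its square root (\code{"pareto"}), or not at all
#' (\code{"none"}).  Constant columns are centered and left undivided.
#'
#' @param x a \linkS4class{BlockMatrix} or matrix.
#' @param method one of \code{"pareto"}, \code{"uv"}, \code{"none"}.
#' @export
setGeneric("centerScale", function(x, method = c("uv", "pareto", "none"))
  standardGeneric("centerScale"))

#' Block variance scaling
#'
#' Divides an entire centered, column-scaled block by one scalar so that its
#' total variance (the sum of its column variances) equals 1, preventing
#' wide blocks from dominating a multiblock model purely by variable count.
#'
#' @param x a \linkS4class{BlockMatrix} or a centered numeric matrix.
#' @export
setGeneric("blockScale", function(x) standardGeneric("blockScale"))

#' Per-sample dilution
#'
#' Multiplies each sample row by a positive per-sample factor, emulating the
#' dilution / biomass effect that probabilistic quotient normalization is
#' designed to remove.
#'
#' @param x a \linkS4class{BlockMatrix} or matrix.
#' @param factors positive numeric vector, one factor per sample.
#' @export
setGeneric("applyDilution", function(x, factors) standardGeneric("applyDilution"))
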
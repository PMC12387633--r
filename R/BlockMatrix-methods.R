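#' @describeIn BlockMatrix the underlying samples x variables matrix
#' @param x a BlockMatrix
#' @export
setMethod("blockValues", "BlockMatrix", function(x) x@values)

#' @describeIn BlockMatrix block identifier
#' @export
setMethod("blockId", "BlockMatrix", function(x) x@blockId)

#' @describeIn BlockMatrix completed preprocessing stages
#' @export
setMethod("blockState", "BlockMatrix", function(x) x@state)

#' @describeIn BlockMatrix stored preprocessing parameters
#' @export
setMethod("preprocParams", "BlockMatrix", function(x) x@params)

#' @describeIn BlockMatrix sample ids (row names)
#' @export
setMethod("sampleNames", "BlockMatrix", function(x) rownames(x@values))

#' @describeIn BlockMatrix variable ids (column names)
#' @export
setMethod("variableNames", "BlockMatrix", function(x) colnames(x@values))

#' @export
setMethod("dim", "BlockMatrix", function(x) dim(x@values))

setMethod("show", "BlockMatrix", function(object) {
  cat(sprintf("BlockMatrix %s: %d samples x %d variables\n",
              object@blockId, nrow(object@values), ncol(object@values)))
  cat("  state:", paste(object@state, collapse = " -> "), "\n")
  if (length(object@params))
    cat("  stored params:", paste(names(object@params), collapse = ", "), "\n")
})

## internal: advance the state chain, refusing to go backwards
.advanceState <- function(bm, newState) {
  st <- union(bm@state, newState)
  bm@state <- .BLOCK_STATES[.BLOCK_STATES %in% st]
  bm
}

.hasState <- function(bm, s) s %in% bm@state

#' @describeIn StudyDesign condition factor, one entry per sample
#' @param x a StudyDesign
#' @export
setMethod("conditions", "StudyDesign", function(x) {
  stats::setNames(x@condition, x@samples)
})

#' @describeIn StudyDesign ordered group labels
#' @export
setMethod("groupLevels", "StudyDesign", function(x) levels(x@condition))

#' @describeIn StudyDesign one-hot dummy response matrix Y
#'   (n samples x g groups; each row sums to 1)
#' @export
setMethod("responseMatrix", "StudyDesign", function(x) {
  g <- levels(x@condition)
  Y <- outer(as.character(x@condition), g, "==") * 1
  dimnames(Y) <- list(x@samples, g)
  Y
})

setMethod("show", "StudyDesign", function(object) {
  tab <- table(object@condition)
  cat(sprintf("StudyDesign: %d samples, %d conditions\n",
              length(object@samples), nlevels(object@condition)))
  print(tab)
})

#' @export
setMethod("length", "StudyDesign", function(x) length(x@samples))

setMethod("show", "MBPLSModel", function(object) {
  cat(sprintf("MBPLSModel: %d blocks (%s), %d components, %d samples\n",
              length(object@blockNames),
              paste(object@blockNames, collapse = ", "),
              object@nComponents, nrow(object@superScores)))
  cat(sprintf("  cumulative R2Y: %s\n",
              paste(sprintf("%.3f", object@r2yCum), collapse = " ")))
})

setMethod("show", "ValidationReport", function(object) {
  cat("ValidationReport\n")
  cat(sprintf("  %-12s %8.4f\n", "R2Y", object@r2y))
  cat(sprintf("  %-12s %8.4f  (%s)\n", "Q2Y", object@q2y, object@scheme))
  cat(sprintf("  %-12s %8.4f\n", "AUROC macro", object@aurocMacro))
  for (g in names(object@aurocClass))
    cat(sprintf("  %-12s %8.4f\n", paste0("AUROC ", g), object@aurocClass[[g]]))
})

#' Extract a ValidationReport as a data frame
#'
#' @param x a ValidationReport
#' @param row.names,optional,... ignored, for generic consistency
#' @export
setMethod("as.data.frame", "ValidationReport",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(metric = c("R2Y", "Q2Y", "AUROC_macro",
                          paste0("AUROC_", names(x@aurocClass))),
               value = c(x@r2y, x@q2y, x@aurocMacro, unname(x@aurocClass)),
               scheme = c("fit", x@scheme, rep(x@scheme, 1 + length(x@aurocClass))),
               stringsAsFactors = FALSE)
  })
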
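## Discriminant-variable machinery: upper-quarter-of-range selection on the
## block weight matrices W, "increased in" group assignment from super-score
## centroids, and angle-preserving biplot coordinates.

.selectionThreshold <- function(absw, rule) {
  absw <- unname(absw)
  switch(rule,
    "range-quarter" = min(absw) + 0.75 * (max(absw) - min(absw)),
    "fraction-of-max" = 0.75 * max(absw),
    "top-quarter-count" = {
      k <- max(1L, ceiling(length(absw) / 4))
      sort(absw, decreasing = TRUE)[k]
    })
}

#' Select discriminant variables
#'
#' For each block and component axis independently, selects the variables
#' whose absolute weight falls within the upper quarter of the range of the
#' absolute weights: \code{|w| >= min|w| + 0.75 * (max|w| - min|w|)}.
#' A degenerate zero-range weight vector selects every variable.
#' Alternative rules: \code{"top-quarter-count"} (top 25\% by count) and
#' \code{"fraction-of-max"} (\code{|w| >= 0.75 max|w|}).
#'
#' @param model a fitted \linkS4class{MBPLSModel}.
#' @param axes component axes to scan (default 1:3, i.e. T1, T2, T3).
#' @param rule selection rule (default \code{"range-quarter"}).
#' @param design optional \linkS4class{StudyDesign}; when given, each
#'   selected variable also receives its "increased in" group set via
#'   \code{\link{assignDirection}}.
#' @return data.frame with columns \code{axis}, \code{block},
#'   \code{variable}, \code{weight}, \code{threshold} and (with a design)
#'   \code{increased_in}.
#' @export
selectDiscriminant <- function(model, axes = seq_len(min(3L, model@nComponents)),
                               rule = c("range-quarter", "top-quarter-count",
                                        "fraction-of-max"),
                               design = NULL) {
  stopifnot(is(model, "MBPLSModel"))
  rule <- match.arg(rule)
  rows <- list()
  for (a in axes) {
    for (b in seq_along(model@blockWeights)) {
      w <- model@blockWeights[[b]][, a]
      if (!length(w)) stop("empty weight vector for block ", model@blockNames[b])
      absw <- abs(w)
      thr <- .selectionThreshold(absw, rule)
      sel <- which(absw >= thr)
      if (!length(sel)) next
      rows[[length(rows) + 1L]] <- data.frame(
        axis = paste0("T", a), block = model@blockNames[b],
        variable = names(w)[sel] %||% as.character(sel),
        weight = unname(w[sel]), threshold = thr,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(axis = character(), block = character(), variable = character(),
               weight = numeric(), threshold = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!is.null(design) && nrow(out)) {
    out$increased_in <- vapply(seq_len(nrow(out)), function(i) {
      a <- as.integer(sub("^T", "", out$axis[i]))
      paste(assignDirection(model, design, axis = a, weightSign = sign(out$weight[i])),
            collapse = "/")
    }, character(1))
  }
  out
}

#' Assign the "increased in" group set of a discriminant variable
#'
#' A variable with a positive weight on an axis points towards the samples
#' with positive super scores on that axis; the groups whose score centroid
#' shares the weight's sign (and clears a noise floor of 0.1 axis-score SD)
#' form the variable's "increased in" coalition.  Groups below the floor
#' are treated as neutral.  If no centroid clears the floor on the weight's
#' side, the floor is dropped; an axis with all centroids at zero is an
#' error.
#'
#' @param model a fitted \linkS4class{MBPLSModel}.
#' @param design the \linkS4class{StudyDesign} used in fitting.
#' @param axis component axis (integer).
#' @param weightSign sign of the variable's weight (+1 or -1).
#' @param floorFrac centroid noise floor as a fraction of the axis score SD.
#' @return character vector of group labels (a single group or a
#'   coalition), in design group order.
#' @export
assignDirection <- function(model, design, axis = 1, weightSign = 1,
                            floorFrac = 0.1) {
  stopifnot(is(model, "MBPLSModel"), is(design, "StudyDesign"))
  t <- model@superScores[, axis]
  cond <- design@condition
  cent <- tapply(t, cond, mean)
  if (all(abs(cent) < .Machine$double.eps * 100))
    stop("all group centroids are zero on axis ", axis)
  floor <- floorFrac * stats::sd(t)
  sameSide <- sign(cent) == sign(weightSign) & abs(cent) > floor
  if (!any(sameSide)) sameSide <- sign(cent) == sign(weightSign)
  if (!any(sameSide)) sameSide <- abs(cent) == max(abs(cent))
  groupLevels(design)[sameSide[groupLevels(design)]]
}

#' Angle-preserving biplot coordinates
#'
#' Produces the variable and sample coordinates behind the model biplots
#' (panels T1/T2 and T2/T3).  Each block's selected-variable weight vectors
#' are multiplied by one uniform positive factor — the block's stored
#' variance divisor, undoing the block normalization — and all variables
#' are then scaled by a common factor to a display radius; sample super
#' scores are likewise uniformly scaled.  Uniform scaling preserves every
#' variable's angle to the component axes exactly.
#'
#' @param model a fitted \linkS4class{MBPLSModel} with >= max(axes)
#'   components.
#' @param selected selection table from \code{\link{selectDiscriminant}}
#'   (default: computed with the default rule on the panel axes).
#' @param axes the two component axes of the panel (default c(1, 2)).
#' @param blockDivisors named per-block divisors to undo (default: taken
#'   from the model's stored preprocessing, else 1).
#' @param displayRadius radius the largest variable vector is scaled to.
#' @return list with \code{variables} (data.frame: block, variable, x, y)
#'   and \code{scores} (data.frame: sample, x, y).
#' @export
biplotCoordinates <- function(model, selected = NULL, axes = c(1, 2),
                              blockDivisors = NULL, displayRadius = 1) {
  stopifnot(is(model, "MBPLSModel"))
  if (length(axes) != 2) stop("a biplot panel needs exactly 2 component axes")
  if (max(axes) > model@nComponents)
    stop("model has fewer components than the requested panel axes")
  if (is.null(selected)) selected <- selectDiscriminant(model, axes = axes)
  if (is.null(blockDivisors)) {
    blockDivisors <- vapply(model@blockNames, function(b) {
      fit <- model@preprocessing[[b]]
      if (!is.null(fit$blockDiv)) fit$blockDiv else 1
    }, numeric(1))
  }
  axisNames <- paste0("T", axes)
  sel <- selected[selected$axis %in% axisNames, , drop = FALSE]
  vars <- unique(sel[, c("block", "variable")])
  if (nrow(vars)) {
    coords <- t(vapply(seq_len(nrow(vars)), function(i) {
      b <- vars$block[i]
      w <- model@blockWeights[[b]][vars$variable[i], axes]
      w * blockDivisors[[b]]
    }, numeric(2)))
    maxR <- max(sqrt(rowSums(coords^2)))
    if (maxR > 0) coords <- coords * (displayRadius / maxR)
    vars$x <- coords[, 1]; vars$y <- coords[, 2]
  } else {
    vars$x <- numeric(0); vars$y <- numeric(0)
  }
  sc <- model@superScores[, axes, drop = FALSE]
  scR <- max(sqrt(rowSums(sc^2)))
  if (scR > 0) sc <- sc * (displayRadius / scR)
  list(variables = vars,
       scores = data.frame(sample = rownames(model@superScores),
                           x = sc[, 1], y = sc[, 2],
                           stringsAsFactors = FALSE))
}

#' Selection stability across leave-one-out folds
#'
#' Refits the model in every leave-one-out fold and measures, for each
#' selected variable, the fraction of folds in which its weight keeps the
#' full-model sign on its axis.  Variables whose sign flips across folds
#' (consistency below \code{minConsistency}) are flagged unstable — the
#' expected behaviour of spurious selections on data without group
#' structure.
#'
#' @param blocks named list of raw \linkS4class{BlockMatrix} objects.
#' @param design the \linkS4class{StudyDesign}.
#' @param selected selection table from \code{\link{selectDiscriminant}}.
#' @param params preprocessing parameters.
#' @param ncomp components.
#' @param minConsistency stability threshold on sign consistency
#'   (default 0.9).
#' @return \code{selected} with added columns \code{sign_consistency} and
#'   \code{stable}.
#' @export
selectionStability <- function(blocks, design, selected,
                               params = preprocessParams(), ncomp = 4,
                               minConsistency = 0.9) {
  cv <- .looCrossValidate(blocks, design, params, ncomp, keepWeights = TRUE)
  pp <- preprocessStudy(blocks, params)
  full <- fitMBPLS(pp$blocks, design, ncomp = ncomp)
  cons <- vapply(seq_len(nrow(selected)), function(i) {
    a <- as.integer(sub("^T", "", selected$axis[i]))
    b <- selected$block[i]; v <- selected$variable[i]
    s0 <- sign(full@blockWeights[[b]][v, a])
    signs <- vapply(cv$foldWeights, function(fw) sign(fw[[b]][v, a]), numeric(1))
    mean(signs == s0)
  }, numeric(1))
  selected$sign_consistency <- cons
  selected$stable <- cons >= minConsistency
  selected
}
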
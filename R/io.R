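## Delimited-text exchange formats: blocks as CSV (samples x variables,
## header of variable ids, first column the sample id), the design as a
## two-column CSV, ground truth and reports as JSON, fragment lists as
## two-column CSV or MGF.

#' Write a block matrix as CSV
#'
#' @param x a \linkS4class{BlockMatrix} or matrix.
#' @param path output file.
#' @export
writeBlockMatrix <- function(x, path) {
  v <- if (is(x, "BlockMatrix")) blockValues(x) else as.matrix(x)
  df <- data.frame(sample = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a block matrix from CSV
#'
#' @param path CSV file (first column sample ids, header of variable ids).
#' @param blockId block identifier to attach.
#' @return a \linkS4class{BlockMatrix} in raw state.
#' @export
readBlockMatrix <- function(path, blockId) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  BlockMatrix(m, blockId)
}

#' Write / read a study design CSV (columns sample, condition)
#'
#' @param design a \linkS4class{StudyDesign}.
#' @param path CSV file.
#' @export
writeStudyDesign <- function(design, path) {
  utils::write.csv(data.frame(sample = design@samples,
                              condition = as.character(design@condition),
                              stringsAsFactors = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeStudyDesign
#' @param levels optional explicit group order (default: order of first
#'   appearance).
#' @export
readStudyDesign <- function(path, levels = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  StudyDesign(df$sample, df$condition, levels = levels)
}

#' Write the ground truth of a synthetic study as JSON
#'
#' @param truth the \code{truth} element of \code{\link{generateStudy}}.
#' @param path output file.
#' @export
writeGroundTruth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an MS2 fragment list
#'
#' Accepts a two-column CSV (m/z, intensity; header optional) or an MGF
#' file (first \code{BEGIN IONS} block; peak lines "mz intensity").
#'
#' @param path input file.
#' @return data.frame with columns \code{mz} and \code{intensity}.
#' @export
readFragments <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (any(grepl("^BEGIN IONS", lines))) {
    i0 <- which(grepl("^BEGIN IONS", lines))[1]
    i1 <- which(grepl("^END IONS", lines))
    i1 <- i1[i1 > i0][1]
    body <- lines[(i0 + 1):(i1 - 1)]
    peaks <- body[grepl("^[0-9]", body)]
    parts <- strsplit(trimws(peaks), "[[:space:]]+")
    return(data.frame(mz = as.numeric(vapply(parts, `[`, "", 1)),
                      intensity = as.numeric(vapply(parts, function(p)
                        if (length(p) > 1) p[2] else "1", "")),
                      stringsAsFactors = FALSE))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        header = !grepl("^[0-9.]", lines[1]))
  df <- df[, 1:2]
  names(df) <- c("mz", "intensity")
  df$mz <- as.numeric(df$mz); df$intensity <- as.numeric(df$intensity)
  df
}
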
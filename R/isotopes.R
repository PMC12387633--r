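## Monoisotopic atomic mass table, shipped as a versioned data file so the
## provenance of every m/z the package prints is auditable.

.isotopeEnv <- new.env(parent = emptyenv())

#' Monoisotopic atomic masses used by the annotation arithmetic
#'
#' Returns the most-abundant-isotope atomic masses (Da) shipped with the
#' package, including the electron mass under the symbol \code{"e"}.
#'
#' @return named numeric vector of masses in Da.
#' @examples
#' isotopeMasses()[["H"]]
#' @export
isotopeMasses <- function() {
  if (is.null(.isotopeEnv$masses)) {
    path <- system.file("extdata", "isotope_masses.csv", package = "MBPLSmetab")
    tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
    .isotopeEnv$masses <- stats::setNames(tab$mass, tab$element)
  }
  .isotopeEnv$masses
}

.electronMass <- function() isotopeMasses()[["e"]]
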
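## Deterministic mass-spectrometric arithmetic: monoisotopic and adduct m/z,
## ppm errors, betaine-lipid headgroup diagnostics and acyl neutral losses.
##
## Electron-mass conventions differ by use.  Fragment formulas printed next
## to observed MS2 peaks (e.g. the DGTA/DGTS headgroup ions C10H22NO5+ at
## 236.1498 and C7H14NO2+ at 144.1025) match electron-NEGLECTED sums at four
## decimals, so monoisotopicMass() neglects the electron by default even for
## cations.  Adduct m/z, by contrast, is proton arithmetic: adductMz()
## subtracts one electron mass per positive charge by default.

#' Parse a molecular formula
#'
#' Turns a Hill-style formula string (e.g. \code{"C10H22NO5"}) into a named
#' element count vector.  Only elements in \code{\link{isotopeMasses}} are
#' accepted.
#'
#' @param formula formula string, or an already-parsed named numeric vector.
#' @return named integer vector of element counts.
#' @examples
#' molecularFormula("C7H14NO2")
#' @export
molecularFormula <- function(formula) {
  if (is.numeric(formula)) {
    counts <- formula
  } else {
    stopifnot(is.character(formula), length(formula) == 1L)
    s <- gsub("[[:space:]+-]", "", formula)
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)
    toks <- regmatches(s, m)[[1]]
    if (!length(toks) || sum(attr(m[[1]], "match.length")) != nchar(s))
      stop("cannot parse formula: ", formula)
    el <- sub("[0-9]*$", "", toks)
    n <- sub("^[A-Za-z]*", "", toks)
    n <- ifelse(n == "", 1L, as.integer(n))
    counts <- tapply(n, el, sum)
    counts <- stats::setNames(as.vector(counts), names(counts))
  }
  known <- setdiff(names(isotopeMasses()), "e")
  bad <- setdiff(names(counts), known)
  if (length(bad)) stop("unsupported element(s): ", paste(bad, collapse = ", "))
  if (any(counts < 0)) stop("negative element count")
  if (sum(counts) < 1) stop("formula must contain at least one atom")
  counts <- counts[counts > 0]
  storage.mode(counts) <- "integer"
  counts[order(names(counts))]
}

## internal: add/subtract parsed formulas; negative results are an error
.combineFormulas <- function(f1, f2, sign = 1L) {
  el <- union(names(f1), names(f2))
  out <- stats::setNames(integer(length(el)), el)
  out[names(f1)] <- f1
  out[names(f2)] <- out[names(f2)] + sign * f2
  if (any(out < 0)) stop("formula combination removes more atoms than present")
  out[out > 0]
}

#' Monoisotopic mass
#'
#' Sum of most-abundant-isotope atomic masses of a molecular formula.  When
#' \code{asCation = TRUE} and \code{electron = TRUE} one electron mass is
#' subtracted; the default neglects the electron, matching the convention
#' used to print fragment-formula masses next to observed MS2 peaks.
#'
#' @param formula formula string or named count vector.
#' @param asCation treat the species as a singly charged cation.
#' @param electron subtract the electron mass for a cation (default FALSE).
#' @return mass in Da.
#' @examples
#' round(monoisotopicMass("C10H22NO5", asCation = TRUE), 4)  # 236.1498
#' round(monoisotopicMass("C7H14NO2", asCation = TRUE), 4)   # 144.1025
#' @export
monoisotopicMass <- function(formula, asCation = FALSE, electron = FALSE) {
  f <- molecularFormula(formula)
  m <- sum(isotopeMasses()[names(f)] * f)
  if (asCation && electron) m <- m - .electronMass()
  unname(m)
}

#' Adduct specification
#'
#' Describes an ionization adduct as a formula delta and a charge.  Built-in
#' names: \code{"[M+H]+"}, \code{"[M+Na]+"}, \code{"[M+K]+"},
#' \code{"[M-H2O+H]+"}, \code{"[M+H2O+K]+"}, \code{"[M+NH4]+"},
#' \code{"[M-H]-"}.
#'
#' @param name adduct name; a built-in name fills \code{add}, \code{lose}
#'   and \code{charge} automatically.
#' @param add,lose formula strings gained / lost relative to M.
#' @param charge non-zero integer charge.
#' @param electron account for electron gain/loss per unit charge
#'   (default TRUE: adduct m/z is proton, not hydrogen-atom, arithmetic).
#' @return an object of class \code{"AdductSpec"} (a list).
#' @export
adductSpec <- function(name = "[M+H]+", add = NULL, lose = NULL,
                       charge = NULL, electron = TRUE) {
  builtins <- list(
    "[M+H]+"     = list(add = "H",    lose = "",    charge = 1L),
    "[M+Na]+"    = list(add = "Na",   lose = "",    charge = 1L),
    "[M+K]+"     = list(add = "K",    lose = "",    charge = 1L),
    "[M-H2O+H]+" = list(add = "H",    lose = "H2O", charge = 1L),
    "[M+H2O+K]+" = list(add = "KH2O", lose = "",    charge = 1L),
    "[M+NH4]+"   = list(add = "NH4",  lose = "",    charge = 1L),
    "[M-H]-"     = list(add = "",     lose = "H",   charge = -1L))
  if (is.null(add) && is.null(lose) && is.null(charge)) {
    if (!name %in% names(builtins)) stop("unknown adduct name: ", name)
    b <- builtins[[name]]
    add <- b$add; lose <- b$lose; charge <- b$charge
  }
  charge <- as.integer(charge)
  if (charge == 0L) stop("adduct charge must be non-zero")
  structure(list(name = name, add = add %||% "", lose = lose %||% "",
                 charge = charge, electron = isTRUE(electron)),
            class = "AdductSpec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Adduct m/z
#'
#' Computes the m/z of a molecule under an adduct:
#' \code{(mass(M) + mass(added) - mass(lost) -/+ z * m_e) / |z|}.
#'
#' @param formula molecular formula of M.
#' @param adduct an \code{\link{adductSpec}} or a built-in adduct name.
#' @return m/z value.
#' @examples
#' round(adductMz("C6H6O2", "[M+H]+"), 4)       # catechol, 111.0441
#' round(adductMz("C5H10O5", "[M-H2O+H]+"), 4)  # ribose, 133.0495
#' @export
adductMz <- function(formula, adduct = "[M+H]+") {
  if (is.character(adduct)) adduct <- adductSpec(adduct)
  stopifnot(inherits(adduct, "AdductSpec"))
  f <- molecularFormula(formula)
  if (nzchar(adduct$add)) f <- .combineFormulas(f, molecularFormula(adduct$add))
  if (nzchar(adduct$lose)) f <- .combineFormulas(f, molecularFormula(adduct$lose), -1L)
  m <- sum(isotopeMasses()[names(f)] * f)
  if (adduct$electron) m <- m - adduct$charge * .electronMass()
  m / abs(adduct$charge)
}

#' Mass error in parts per million
#'
#' @param observed observed m/z.
#' @param theoretical theoretical m/z (> 0).
#' @return \code{(observed - theoretical) / theoretical * 1e6}.
#' @examples
#' round(ppmError(111.0437, 111.0441), 1)  # -3.6
#' @export
ppmError <- function(observed, theoretical) {
  stopifnot(all(theoretical > 0))
  (observed - theoretical) / theoretical * 1e6
}

#' Fatty acyl candidate
#'
#' Describes a fatty acyl substituent by its carbon count, double-bond count
#' and extra oxygens, and derives the neutral-loss formulas: the free acid
#' (-RCOOH, C_c H_{2c-2d} O_{2+o}) and the ketene (-R=C=O, the acid minus
#' H2O).
#'
#' @param carbons carbon count (>= 2).
#' @param doubleBonds number of C=C double bonds (>= 0).
#' @param extraOxygens additional oxygens (hydroxy/oxo chains), default 0.
#' @return an object of class \code{"AcylCandidate"} with the acid and
#'   ketene formulas and masses.
#' @examples
#' acylCandidate(14, 0)  # myristic acid: acid C14H28O2, ketene C14H26O
#' @export
acylCandidate <- function(carbons, doubleBonds = 0, extraOxygens = 0) {
  carbons <- as.integer(carbons); doubleBonds <- as.integer(doubleBonds)
  if (carbons < 2L) stop("acyl candidates need >= 2 carbons")
  if (doubleBonds < 0L) stop("double-bond count must be >= 0")
  h <- 2L * carbons - 2L * doubleBonds
  if (h < 2L) stop("too many double bonds for the chain length")
  acid <- c(C = carbons, H = h, O = 2L + as.integer(extraOxygens))
  ketene <- c(C = carbons, H = h - 2L, O = 1L + as.integer(extraOxygens))
  label <- sprintf("%d:%d%s", carbons, doubleBonds,
                   if (extraOxygens > 0) sprintf(";O%d", extraOxygens) else "")
  structure(list(label = label, carbons = carbons, doubleBonds = doubleBonds,
                 extraOxygens = as.integer(extraOxygens),
                 acidFormula = acid, keteneFormula = ketene,
                 acidMass = monoisotopicMass(acid),
                 keteneMass = monoisotopicMass(ketene)),
            class = "AcylCandidate")
}

#' @export
print.AcylCandidate <- function(x, ...) {
  cat(sprintf("AcylCandidate %s: acid %.4f Da, ketene %.4f Da\n",
              x$label, x$acidMass, x$keteneMass))
  invisible(x)
}

#' Match acyl neutral losses in an MS2 spectrum
#'
#' For each fatty acyl candidate, looks for fragments at
#' \code{precursor - mass(acid)} and \code{precursor - mass(ketene)} within
#' a ppm tolerance.  This is the arithmetic that identifies the fatty-acid
#' substituents of betaine lipids from their MS2 spectra.
#'
#' @param precursorMz precursor ion m/z.
#' @param fragments numeric vector of fragment m/z values.
#' @param candidates list of \code{\link{acylCandidate}} objects.
#' @param tolPpm matching tolerance in ppm (> 0), default 10.
#' @return data.frame with one row per candidate x matched loss type:
#'   columns \code{acyl}, \code{loss} ("acid"/"ketene"), \code{expectedMz},
#'   \code{matchedMz}, \code{errorPpm}.  Zero rows when nothing matches.
#' @export
matchNeutralLosses <- function(precursorMz, fragments, candidates, tolPpm = 10) {
  stopifnot(tolPpm > 0)
  if (inherits(candidates, "AcylCandidate")) candidates <- list(candidates)
  if (!length(candidates)) stop("empty candidate list")
  rows <- list()
  for (cand in candidates) {
    for (loss in c("acid", "ketene")) {
      lm <- if (loss == "acid") cand$acidMass else cand$keteneMass
      exp_mz <- precursorMz - lm
      if (exp_mz <= 0 || !length(fragments)) next
      err <- ppmError(fragments, exp_mz)
      hit <- which(abs(err) <= tolPpm)
      if (length(hit)) {
        best <- hit[which.min(abs(err[hit]))]
        rows[[length(rows) + 1L]] <- data.frame(
          acyl = cand$label, loss = loss, expectedMz = exp_mz,
          matchedMz = fragments[best], errorPpm = err[best],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(acyl = character(), loss = character(),
                      expectedMz = numeric(), matchedMz = numeric(),
                      errorPpm = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$acyl, out$loss), , drop = FALSE]
}

#' Detect the betaine-lipid headgroup
#'
#' DGTA/DGTS betaine lipids (isobaric; never distinguished here) show two
#' diagnostic headgroup fragments in positive-mode MS2: m/z 236.1498
#' (C10H22NO5+) and m/z 144.1025 (C7H14NO2+).  Returns whether the
#' diagnostics are present in a fragment list within a ppm tolerance.
#'
#' @param fragments numeric vector of fragment m/z values.
#' @param tolPpm tolerance in ppm (> 0), default 5.
#' @param policy \code{"both"} (default) requires both ions,
#'   \code{"any"} accepts either.
#' @return list with \code{detected} (logical), \code{matched} (data.frame
#'   of diagnostic ion, theoretical and matched m/z, ppm error) and
#'   \code{headgroup} ("DGTA/S" when detected, NA otherwise).
#' @export
detectBetaineHeadgroup <- function(fragments, tolPpm = 5,
                                   policy = c("both", "any")) {
  stopifnot(tolPpm > 0)
  policy <- match.arg(policy)
  diag <- c("C10H22NO5" = monoisotopicMass("C10H22NO5", asCation = TRUE),
            "C7H14NO2" = monoisotopicMass("C7H14NO2", asCation = TRUE))
  rows <- lapply(names(diag), function(f) {
    theo <- diag[[f]]
    if (!length(fragments)) return(NULL)
    err <- ppmError(fragments, theo)
    hit <- which(abs(err) <= tolPpm)
    if (!length(hit)) return(NULL)
    best <- hit[which.min(abs(err[hit]))]
    data.frame(ion = f, theoreticalMz = theo, matchedMz = fragments[best],
               errorPpm = err[best], stringsAsFactors = FALSE)
  })
  matched <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(matched))
    matched <- data.frame(ion = character(), theoreticalMz = numeric(),
                          matchedMz = numeric(), errorPpm = numeric(),
                          stringsAsFactors = FALSE)
  nHit <- nrow(matched)
  detected <- if (policy == "both") nHit == length(diag) else nHit >= 1L
  list(detected = detected, matched = matched,
       headgroup = if (detected) "DGTA/S" else NA_character_)
}
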
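#' n-Alkane retention ladder
#'
#' Retention times of a homologous n-alkane series used to express GC
#' retention on the Kovats / Van den Dool-Kratz index scale.
#'
#' @param carbons integer carbon numbers (>= 2 rungs, strictly increasing).
#' @param rt retention times, strictly increasing, same length.
#' @return an object of class \code{"AlkaneLadder"}.
#' @export
alkaneLadder <- function(carbons, rt) {
  carbons <- as.integer(carbons)
  stopifnot(length(carbons) == length(rt), length(carbons) >= 2L)
  o <- order(carbons)
  carbons <- carbons[o]; rt <- rt[o]
  if (any(diff(carbons) <= 0L)) stop("duplicate carbon numbers in ladder")
  if (any(diff(rt) <= 0)) stop("ladder retention times must be strictly increasing")
  structure(list(carbons = carbons, rt = rt), class = "AlkaneLadder")
}

#' @export
print.AlkaneLadder <- function(x, ...) {
  cat(sprintf("AlkaneLadder: C%d..C%d, rt %.2f..%.2f\n",
              min(x$carbons), max(x$carbons), min(x$rt), max(x$rt)))
  invisible(x)
}

#' Kovats (Van den Dool-Kratz) retention index
#'
#' Linear temperature-programmed convention:
#' \code{RI = 100 * (n + (rt - rt_n) / (rt_{n+1} - rt_n))} using the
#' bracketing alkanes C_n and C_{n+1}.  An alkane rung maps exactly to
#' \code{100 * n}.
#'
#' @param rt retention time(s) to convert.
#' @param ladder an \code{\link{alkaneLadder}}.
#' @param extrapolate allow rt outside the ladder span (uses the nearest
#'   alkane pair); default FALSE (error).
#' @return retention index value(s).
#' @examples
#' lad <- alkaneLadder(14:18, c(10, 12, 14.5, 17, 19))
#' kovatsRI(14.5, lad)  # 1600
#' @export
kovatsRI <- function(rt, ladder, extrapolate = FALSE) {
  stopifnot(inherits(ladder, "AlkaneLadder"))
  vapply(rt, function(r) {
    if (r < min(ladder$rt) || r > max(ladder$rt)) {
      if (!extrapolate)
        stop(sprintf("rt %.3f outside ladder span [%.3f, %.3f]",
                     r, min(ladder$rt), max(ladder$rt)))
      i <- if (r < min(ladder$rt)) 1L else length(ladder$rt) - 1L
    } else {
      i <- max(which(ladder$rt <= r))
      if (i == length(ladder$rt)) i <- i - 1L  # exactly at the top rung
    }
    n0 <- ladder$carbons[i]; n1 <- ladder$carbons[i + 1L]
    r0 <- ladder$rt[i]; r1 <- ladder$rt[i + 1L]
    # non-consecutive rungs interpolate across the full carbon gap
    100 * (n0 + (n1 - n0) * (r - r0) / (r1 - r0))
  }, numeric(1))
}
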
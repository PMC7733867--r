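## ProbVector plumbing: construction and the rescale discipline.  Raw
## backward/forward vectors decay geometrically with the number of events;
## every epoch solve and event update therefore folds the running maximum
## into logScale so the stored values stay in a safe floating-point window.

newProbVector <- function(values, logScale = 0, k = 0L, t = 0) {
  rescaleProbVector(new("ProbVector", values = values, logScale = logScale,
                        k = as.integer(k), t = t))
}

rescaleProbVector <- function(pv) {
  m <- max(pv@values)
  if (m > 0 && (m > 1e3 || m < 1e-3)) {
    pv@values <- pv@values / m
    pv@logScale <- pv@logScale + log(m)
  }
  pv
}

## TRUE when an event with zero rate wiped the vector out (zero-density
## signal: the data are impossible under the parameters)
isZeroVector <- function(pv) max(pv@values) == 0

#' Truncation adequacy check
#'
#' The truncation N is adequate when the top entry of a recorded vector is
#' negligible against its maximum; otherwise probability mass is leaking
#' through the boundary and N should be enlarged.
#'
#' @param pv a [ProbVector-class].
#' @param tol relative tolerance on the top entry.
#' @return TRUE (invisibly); warns when the tail is not negligible.
#' @keywords internal
checkTruncationTail <- function(pv, tol = 1e-10) {
  v <- pv@values
  if (max(v) > 0 && v[length(v)] / max(v) > tol)
    warning(sprintf(
      "truncation tail at t=%.4g: values[N]/max = %.2e > %.0e; increase N",
      pv@t, v[length(v)] / max(v), tol), call. = FALSE)
  invisible(TRUE)
}
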
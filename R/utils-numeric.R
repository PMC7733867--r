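## Small numerical helpers shared across the backward/forward traversals.

#' Numerically stable log(sum(exp(x)))
#'
#' @param x numeric vector (may contain -Inf).
#' @return log of the sum of exp(x).
#' @keywords internal
logSumExp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## Truncated product of two power series (coefficient vectors indexed 0..N).
## Only coefficients up to the common truncation order are kept.
seriesMultiply <- function(a, b) {
  n <- length(a)
  out <- numeric(n)
  for (j in seq_len(n)) {
    out[j] <- sum(a[seq_len(j)] * b[j:1L])
  }
  out
}

## Action of the matrix exponential e^{dt A} on a vector, for the tridiagonal
## generator-like matrices of the truncated master equations, computed by
## uniformization: A = B - m I with B >= 0 elementwise, so
## e^{dt A} v = e^{-m dt} sum_j (dt^j / j!) B^j v, a series of non-negative
## terms evaluated with running rescaling.  Returns list(values, logScale).
##
## dg, up, dn are the diagonal (length N+1), superdiagonal (length N) and
## subdiagonal (length N) of A, so that (A v)[i] = dg[i] v[i] + up[i] v[i+1]
## + dn[i-1] v[i-1] (1-based).
expmActionTridiag <- function(dg, up, dn, v, dt, tol = 1e-16) {
  if (dt == 0 || max(abs(v)) == 0) {
    return(list(values = v, logScale = 0))
  }
  stopifnot(dt > 0, all(up >= 0), all(dn >= 0))
  n <- length(v)
  m <- max(-dg)                      # uniformization constant
  bd <- dg + m                       # shifted diagonal, >= 0
  Bv <- function(w) {
    out <- bd * w
    out[seq_len(n - 1L)] <- out[seq_len(n - 1L)] + up * w[-1L]
    out[-1L] <- out[-1L] + dn * w[seq_len(n - 1L)]
    out
  }
  term <- v
  acc <- v
  logScale <- -m * dt
  j <- 0L
  jmin <- m * dt                     # series terms peak near j = m dt
  repeat {
    j <- j + 1L
    term <- Bv(term) * (dt / j)
    acc <- acc + term
    mt <- max(abs(term))
    ma <- max(abs(acc))
    if (ma > 1e250) {                # fold scale out before overflow
      acc <- acc / ma
      term <- term / ma
      logScale <- logScale + log(ma)
      mt <- mt / ma
      ma <- 1
    }
    if (j > jmin && mt <= tol * ma) break
    if (j > 1e6) stop("uniformization series failed to converge")
  }
  list(values = acc, logScale = logScale)
}

## Lower quantile of a discrete distribution on `support` with weights `prob`:
## smallest support value whose CDF reaches p.
lowerQuantile <- function(support, prob, p) {
  cdf <- cumsum(prob)
  support[which(cdf >= p - 1e-12)[1L]]
}
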
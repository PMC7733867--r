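## Forward traversal: M_t(i) = P(T_t-up, O_t-up, I_t = k_t + i), propagated
## from the origin to the present.
##
## Across an event-free epoch the generating function M^(t, z) solves a
## first-order PDE whose characteristics give the closed epoch solution
##   M^(t, z) = F(u(s, z)) * R(s, z)^k,   s = t_top - t,
## with F the generating function at the top of the epoch.  Writing
## E = exp(-Delta s), c0 = x2 - x1 E, c1 = 1 - E, u and R are rational:
##   u(s, z) = (n0 - n1 z) / (c0 - c1 z),  n0 = x1 x2 c1, n1 = x1 - x2 E,
##   R(s, z) = (Delta/lambda)^2 E / (c0 - c1 z)^2.
## The truncated coefficient vector of M^ is extracted by power-series
## arithmetic: the series of u has non-negative coefficients
##   [z^0] u = n0/c0,  [z^j] u = E (Delta/lambda)^2 c1^(j-1) / c0^(j+1),
## the series of R^k is a negative-binomial series, and F(u) is evaluated
## by Horner on truncated series.  All terms are non-negative, so the
## extraction is free of the cancellation that plagues the equivalent
## closed double sum over falling factorials.

#' Initial forward vector at the origin
#'
#' At the origin the process starts with the single (observed) origin
#' lineage and no hidden individuals: `M_tOr(i) = 1{i = 0}` with `k = 1`.
#'
#' @param N truncation of the hidden-individual count.
#' @param tOr origin time stamp for the vector.
#' @return a [ProbVector-class].
#' @export
initM <- function(N, tOr = 0) {
  newProbVector(c(1, numeric(N)), k = 1L, t = tOr)
}

## series of u(s, z) and of R(s, z)^k, truncated at order N
uSeries <- function(s, params, N) {
  E <- exp(-params@Delta * s)
  c0 <- params@x2 - params@x1 * E
  c1 <- 1 - E
  out <- numeric(N + 1L)
  out[1L] <- params@x1 * params@x2 * c1 / c0
  if (N >= 1L)
    out[-1L] <- E * (params@Delta / params@lambda)^2 / c0^2 *
      cumprod(c(1, rep(c1 / c0, N - 1L)))
  out
}

rkSeriesLog <- function(s, params, k, N) {
  E <- exp(-params@Delta * s)
  c0 <- params@x2 - params@x1 * E
  c1 <- 1 - E
  j <- 0:N
  k * (2 * log(params@Delta / params@lambda) - params@Delta * s) +
    lchoose(2 * k + j - 1, j) +
    ifelse(j == 0, 0, j * log(c1)) - (2 * k + j) * log(c0)
}

#' Propagate a forward vector across an event-free epoch
#'
#' Applies the analytic epoch solution of the generating function (see the
#' file header): the vector at the top of the epoch defines
#' `F(z) = sum_l M(l) z^l`, and the returned vector holds the Taylor
#' coefficients at `z = 0` of `F(u(dt, z)) R(dt, z)^k`, computed by
#' truncated power-series arithmetic.  `dt = 0` is the identity (since
#' `u(0, z) = z`, `R(0, z) = 1`).
#'
#' @param M a [ProbVector-class] at the top of the epoch (its `k` slot is
#'   the epoch lineage count).
#' @param dt epoch duration, >= 0; the result is stamped at `M@t - dt`.
#' @param params a [BDParams-class].
#' @param method `"series"` is the analytic generating-function
#'   extraction; `"uniformization"` solves the truncated forward master
#'   equation (whose generator is the exact transpose of the backward
#'   one) by matrix-exponential action, which scales linearly in the
#'   truncation and is preferred for large N.  `"auto"` (default) picks
#'   the series below N = 150.
#' @return the propagated [ProbVector-class].
#' @export
evolveMEpoch <- function(M, dt, params,
                         method = c("auto", "series", "uniformization")) {
  stopifnot(is(M, "ProbVector"), dt >= 0)
  method <- match.arg(method)
  if (dt == 0 || isZeroVector(M)) { M@t <- M@t - dt; return(M) }
  N <- length(M@values) - 1L
  if (method == "auto")
    method <- if (N <= 150L) "series" else "uniformization"
  if (method == "uniformization") {
    k <- M@k
    i <- 0:N
    res <- expmActionTridiag(
      dg = -params@gamma * (k + i),
      up = params@mu * seq_len(N),
      dn = params@lambda * (2 * k + seq_len(N) - 1),
      v = M@values, dt = dt)
    return(newProbVector(res$values,
                         logScale = M@logScale + res$logScale,
                         k = k, t = M@t - dt))
  }
  us <- uSeries(dt, params, N)
  ## Horner: F(u) as a truncated series in z.  Every step multiplies by
  ## the same series, so build its lower-triangular Toeplitz matrix once
  ## and let BLAS carry the mat-vecs.
  idx <- outer(seq_len(N + 1L), seq_len(N + 1L), `-`) + 1L
  U <- matrix(0, N + 1L, N + 1L)
  keep <- idx >= 1L
  U[keep] <- us[idx[keep]]
  ## Horner only over the occupied support of F (top zeros are inert)
  lmax <- max(which(M@values > 1e-18 * max(M@values)))
  S <- c(M@values[lmax], numeric(N))
  if (lmax > 1L) for (l in (lmax - 1L):1L) {
    S <- drop(U %*% S)
    S[1L] <- S[1L] + M@values[l]
  }
  lrk <- rkSeriesLog(dt, params, M@k, N)
  shift <- max(lrk)
  out <- seriesMultiply(S, exp(lrk - shift))
  newProbVector(out, logScale = M@logScale + shift, k = M@k, t = M@t - dt)
}

#' Apply a punctual-event update to a forward vector
#'
#' Crossing an event forward in time (from above to below): removed leaf
#' `psi r` with `k -> k - 1`; non-removed leaf
#' `M(i) -> psi (1 - r) M(i - 1)` (bottom entry 0, `k -> k - 1`); sampled
#' ancestor `psi (1 - r)`; removed occurrence
#' `M(i) -> omega r (i + 1) M(i + 1)` (top entry 0); non-removed
#' occurrence `omega (1 - r) (k + i)`; branching `lambda` with
#' `k -> k + 1`; the present-day update `rho^k0 (1 - rho)^i`.  Unknown
#' removal labels sum the two labeled updates.
#'
#' @param M a [ProbVector-class] just above the event.
#' @param kind event kind (see [EventSchedule-class]), or `"present"`.
#' @param params a [BDParams-class].
#' @return the updated [ProbVector-class] just below the event.
#' @export
updateMEvent <- function(M, kind, params) {
  v <- M@values
  N <- length(v) - 1L
  i <- 0:N
  k <- M@k
  psi <- params@psi; omega <- params@omega; r <- params@r
  shiftUp <- c(v[-1L], 0)            # M(i + 1), with M(N + 1) := 0
  shiftDn <- c(0, v[-(N + 1L)])      # M(i - 1), with M(-1) := 0
  new <- switch(kind,
    removed_leaf = psi * r * v,
    nonremoved_leaf = psi * (1 - r) * shiftDn,
    unknown_leaf = psi * r * v + psi * (1 - r) * shiftDn,
    sampled_ancestor = psi * (1 - r) * v,
    removed_occurrence = omega * r * (i + 1) * shiftUp,
    nonremoved_occurrence = omega * (1 - r) * (k + i) * v,
    unknown_occurrence = omega * r * (i + 1) * shiftUp +
      omega * (1 - r) * (k + i) * v,
    branching = params@lambda * v,
    present = params@rho^k * (1 - params@rho)^i * v,
    stop("not a forward event kind: ", kind))
  knew <- if (kind == "present") k else k - kindKStep[[kind]]
  newProbVector(new, logScale = M@logScale, k = knew, t = M@t)
}

#' Forward sweep over a schedule
#'
#' Runs the full forward traversal from the origin to the present,
#' recording the vector at every grid time on its present side (i.e. after
#' the event update when the grid time coincides with a data event).  At
#' the present the vector is recorded before the rho-update, which is
#' carried by the backward initial vector instead, so that the recorded
#' backward and forward vectors at any shared grid time refer to the same
#' instant and satisfy `sum_i L(i) M(i) = P(T, O)` identically.
#'
#' @inheritParams computeL
#' @return a list as in [computeL()]: `vectors` and `gridTimes` in
#'   ascending time order, `final` (the vector just above the present),
#'   and `logDensity` (`log sum_i rho^k0 (1 - rho)^i M_0(i)`).
#' @export
computeM <- function(schedule, params, N, checkTail = TRUE) {
  ev <- schedule@events
  kEp <- schedule@kEpoch
  m <- nrow(ev)
  M <- initM(N, tOr = schedule@tOr)
  aborted <- FALSE
  vectors <- list(); gridTimes <- numeric()
  if (ev$grid[m]) { vectors <- list(M); gridTimes <- ev$time[m] }
  for (h in (m - 1L):1L) {
    M@k <- kEp[h]
    M <- evolveMEpoch(M, ev$time[h + 1L] - ev$time[h], params)
    if (ev$kind[h] == "present") {
      if (ev$grid[h]) { vectors <- c(vectors, M); gridTimes <- c(gridTimes, 0) }
      M <- updateMEvent(M, "present", params)
      break
    }
    if (ev$kind[h] != "grid")
      M <- updateMEvent(M, ev$kind[h], params)
    if (ev$grid[h]) {
      if (checkTail) checkTruncationTail(M)
      vectors <- c(vectors, M)
      gridTimes <- c(gridTimes, ev$time[h])
    }
    if (isZeroVector(M)) {
      warning("zero-density event update at t = ", ev$time[h],
              " (", ev$kind[h], "): the data are impossible under these ",
              "parameters", call. = FALSE)
      aborted <- TRUE
      break
    }
  }
  logDens <- if (aborted || isZeroVector(M)) -Inf
             else log(sum(M@values)) + M@logScale
  ord <- order(gridTimes)
  list(vectors = vectors[ord], gridTimes = gridTimes[ord], final = M,
       logDensity = logDens)
}

#' Log joint density of the data via the forward traversal
#'
#' The forward sweep evaluated at the present returns
#' `sum_i rho^k0 (1 - rho)^i M_0(i)`, the joint probability density of the
#' reconstructed tree and the occurrence record; it must agree with
#' [logDensityBackward()] up to truncation error.
#'
#' @inheritParams logDensityBackward
#' @return the log density (scalar; `-Inf` for impossible data).
#' @export
logDensityForward <- function(schedule, params, N,
                              conditionOnSampling = FALSE) {
  out <- computeM(schedule, params, N, checkTail = FALSE)
  ld <- out$logDensity
  if (conditionOnSampling)
    ld <- ld - log1p(-probNoSample(params@tOr, params))
  ld
}

#' Closed-form forward vector without occurrence sampling
#'
#' When `omega = 0` the generating function stays a finite product of
#' powers of `u` and `R` across the whole traversal, and the coefficient
#' vector follows a two-term recursion driven by the log-derivative
#' coefficients of [epochCoeffs()]: with `v` sampled ancestors, `w`
#' removed leaves (times `W`), `x` branchings (times `X`) and `y`
#' non-removed leaves (times `Y`) at times above `t`,
#' `M_t(0) = lambda^x psi^(v+w+y) r^w (1-r)^(v+y)
#'           prod_(X U {tOr}) R(tj - t, 0) prod_W R(tj - t, 0)^-1
#'           prod_Y u(tj - t, 0) / R(tj - t, 0)`
#' and `M_t(i) = (1/i) sum_a M_t(i - a) C(a)` with
#' `C(a) = 2 sum_(X U {tOr}) a_(tj-t)^a - 2 sum_W a_(tj-t)^a
#'         - sum_Y (a_(tj-t)^a + b_(tj-t)^a)`.
#'
#' @inheritParams closedFormLNoOmega
#' @param side `"below"` counts an event exactly at `t` as already crossed
#'   (the value `M(t-)`, matching [computeM()]'s recording convention);
#'   `"above"` gives `M(t+)`.
#' @return a [ProbVector-class] at time `t`.
#' @export
closedFormMNoOmega <- function(schedule, params, t, iMax,
                               side = c("below", "above")) {
  if (params@omega > 0) stop("closed form requires omega = 0")
  side <- match.arg(side)
  ev <- schedule@events
  sel <- if (side == "below") ev$time >= t & ev$time < schedule@tOr
         else ev$time > t & ev$time < schedule@tOr
  if (any(sel & ev$kind %in% c("removed_occurrence", "nonremoved_occurrence",
                               "unknown_occurrence")))
    stop("closed form requires an empty occurrence record")
  if (any(sel & ev$kind %in% c("unknown_leaf", "unknown_occurrence")))
    stop("closed form requires labeled removal statuses")
  v <- sum(sel & ev$kind == "sampled_ancestor")
  w <- sum(sel & ev$kind == "removed_leaf")
  x <- sum(sel & ev$kind == "branching")
  y <- sum(sel & ev$kind == "nonremoved_leaf")
  W <- ev$time[sel & ev$kind == "removed_leaf"] - t
  X <- c(ev$time[sel & ev$kind == "branching"], schedule@tOr) - t
  Y <- ev$time[sel & ev$kind == "nonremoved_leaf"] - t
  R0 <- function(s) singleSampleRatio(s, params, z = 0)
  u0 <- function(s) probNoSample(s, params, z = 0)
  logM0 <- powLog(x, params@lambda) +
    powLog(v + w + y, params@psi) +
    powLog(w, params@r) + powLog(v + y, 1 - params@r) +
    sum(log(R0(X))) - sum(log(R0(W))) +
    sum(log(u0(Y)) - log(R0(Y)))
  vals <- numeric(iMax + 1L)
  vals[1L] <- 1
  if (iMax >= 1L) {
    cf <- function(s) epochCoeffs(s, params)
    for (i in seq_len(iMax)) {
      al <- seq_len(i)
      Ca <- vapply(al, function(a) {
        2 * sum(cf(X)$a^a) - 2 * sum(cf(W)$a^a) -
          sum(cf(Y)$a^a + cf(Y)$b^a)
      }, numeric(1))
      vals[i + 1L] <- sum(vals[i:1] * Ca) / i
    }
  }
  kt <- x - w - y + 1L               # lineages at t: one per line reaching t
  newProbVector(pmax(vals, 0), logScale = logM0, k = as.integer(kt), t = t)
}
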
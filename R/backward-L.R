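## Backward traversal: L_t(i) = P(T_t-down, O_t-down | I_t = k_t + i),
## propagated from the present to the origin through the truncated master
## equation (tridiagonal generator, solved by matrix-exponential action)
## and the per-event multiplicative updates.

#' Initial backward vector at the present
#'
#' At t = 0 the data below are the k0 present-day tips, so
#' `L_0(i) = rho^k0 (1 - rho)^i`: every tip must be rho-sampled and every
#' hidden survivor missed.
#'
#' @param k0 number of present-day tips.
#' @param rho present-day sampling probability.
#' @param N truncation of the hidden-individual count.
#' @return a [ProbVector-class] at t = 0 with `k = k0`.
#' @export
initL <- function(k0, rho, N) {
  if (rho == 0 && k0 > 0)
    stop("impossible data: rho = 0 cannot produce present-day tips")
  i <- 0:N
  newProbVector(rho^k0 * (1 - rho)^i, k = k0, t = 0)
}

#' Propagate a backward vector across an event-free epoch
#'
#' Solves `dL/dt = A L` over a duration `dt` (t increasing into the past),
#' where A is the truncated tridiagonal generator with diagonal
#' `-gamma (k + i)`, superdiagonal `lambda (2k + i)` and subdiagonal
#' `mu i`.  The action of `exp(dt A)` is computed by uniformization; the
#' missing flux above the truncation bound makes the (one-sided) bias of
#' the truncation.
#'
#' @param L a [ProbVector-class] (its `k` slot is the epoch lineage count).
#' @param dt epoch duration, >= 0.
#' @param params a [BDParams-class].
#' @return the propagated [ProbVector-class] at time `L@t + dt`.
#' @export
evolveLEpoch <- function(L, dt, params) {
  stopifnot(is(L, "ProbVector"), dt >= 0)
  if (dt == 0 || isZeroVector(L)) { L@t <- L@t + dt; return(L) }
  N <- length(L@values) - 1L
  k <- L@k
  i <- 0:N
  res <- expmActionTridiag(
    dg = -params@gamma * (k + i),
    up = params@lambda * (2 * k + i[1:N]),
    dn = params@mu * seq_len(N),
    v = L@values, dt = dt)
  newProbVector(res$values, logScale = L@logScale + res$logScale,
                k = k, t = L@t + dt)
}

#' Apply a punctual-event update to a backward vector
#'
#' Crossing an event backward in time multiplies the vector by the event's
#' rate factor and, for events that exchange an individual between the
#' hidden pool and the tree, shifts the index: removed leaf `psi r`;
#' non-removed leaf `psi (1 - r) L(i + 1)` (top entry set to 0); sampled
#' ancestor `psi (1 - r)`; removed occurrence `omega r i L(i - 1)` (zero at
#' i = 0); non-removed occurrence `omega (1 - r) (k + i)`; branching
#' `lambda` with `k -> k + 1`.  Unknown removal labels sum the two labeled
#' updates.  A zero rate (e.g. a leaf with psi = 0) yields the zero vector,
#' the zero-density signal.
#'
#' @param L a [ProbVector-class] just below the event.
#' @param kind event kind (see [EventSchedule-class]).
#' @param params a [BDParams-class].
#' @return the updated [ProbVector-class] just above the event.
#' @export
updateLEvent <- function(L, kind, params) {
  v <- L@values
  N <- length(v) - 1L
  i <- 0:N
  k <- L@k
  psi <- params@psi; omega <- params@omega; r <- params@r
  shiftUp <- c(v[-1L], 0)            # L(i + 1), with L(N + 1) := 0
  shiftDn <- c(0, v[-(N + 1L)])      # L(i - 1), with L(-1) := 0
  new <- switch(kind,
    removed_leaf = psi * r * v,
    nonremoved_leaf = psi * (1 - r) * shiftUp,
    unknown_leaf = psi * r * v + psi * (1 - r) * shiftUp,
    sampled_ancestor = psi * (1 - r) * v,
    removed_occurrence = omega * r * i * shiftDn,
    nonremoved_occurrence = omega * (1 - r) * (k + i) * v,
    unknown_occurrence = omega * r * i * shiftDn +
      omega * (1 - r) * (k + i) * v,
    branching = params@lambda * v,
    stop("not a data event kind: ", kind))
  knew <- k + kindKStep[[kind]]
  newProbVector(new, logScale = L@logScale, k = knew, t = L@t)
}

#' Backward sweep over a schedule
#'
#' Runs the full backward traversal from the present to the origin,
#' recording the vector at every grid time on its present side (i.e. after
#' the epoch solve, before the event update when the grid time coincides
#' with a data event).
#'
#' @param schedule an [EventSchedule-class].
#' @param params a [BDParams-class].
#' @param N truncation of the hidden-individual count.
#' @param checkTail warn when the truncation tail is not negligible.
#' @return a list with `vectors` (list of [ProbVector-class], one per grid
#'   time, in schedule order), `gridTimes`, `final` (the vector at the
#'   origin) and `logDensity` (`log L_tOr(0)`, the log joint density of the
#'   data; `-Inf` when an event of zero rate was hit).
#' @export
computeL <- function(schedule, params, N, checkTail = TRUE) {
  ev <- schedule@events
  kEp <- schedule@kEpoch
  L <- initL(schedule@k0, params@rho, N)
  aborted <- FALSE
  vectors <- list(); gridTimes <- numeric()
  if (ev$grid[1L]) { vectors <- list(L); gridTimes <- 0 }
  for (h in 2:nrow(ev)) {
    L <- evolveLEpoch(L, ev$time[h] - ev$time[h - 1L], params)
    L@k <- kEp[h - 1L]               # unchanged by the solve; keep in sync
    if (ev$grid[h]) {
      if (checkTail) checkTruncationTail(L)
      vectors <- c(vectors, L)
      gridTimes <- c(gridTimes, ev$time[h])
    }
    if (!ev$kind[h] %in% c("grid", "origin"))
      L <- updateLEvent(L, ev$kind[h], params)
    if (isZeroVector(L)) {
      warning("zero-density event update at t = ", ev$time[h],
              " (", ev$kind[h], "): the data are impossible under these ",
              "parameters", call. = FALSE)
      aborted <- TRUE
      break
    }
  }
  logDens <- if (aborted || isZeroVector(L)) -Inf
             else log(L@values[1L]) + L@logScale
  list(vectors = vectors, gridTimes = gridTimes, final = L,
       logDensity = logDens)
}

#' Log joint density of the data via the backward traversal
#'
#' The backward sweep evaluated at the origin returns `L_tOr(0)`, the joint
#' probability density of the reconstructed tree and the occurrence record.
#' With `conditionOnSampling = TRUE` the density is conditioned on
#' observing at least one sample, i.e. divided by `1 - u(tOr, 1 - rho)`.
#'
#' @inheritParams computeL
#' @param conditionOnSampling condition on at least one sample.
#' @return the log density (scalar; `-Inf` for impossible data).
#' @export
logDensityBackward <- function(schedule, params, N,
                               conditionOnSampling = FALSE) {
  out <- computeL(schedule, params, N, checkTail = FALSE)
  ld <- out$logDensity
  if (conditionOnSampling)
    ld <- ld - log1p(-probNoSample(params@tOr, params))
  ld
}

## counts and time sets of the tree events in a half-open time window
eventCounts <- function(schedule, lower = -Inf, upper = Inf) {
  ev <- schedule@events
  sel <- ev$time > lower & ev$time < upper
  list(v = sum(sel & ev$kind == "sampled_ancestor"),
       w = sum(sel & ev$kind == "removed_leaf"),
       x = sum(sel & ev$kind == "branching"),
       y = sum(sel & ev$kind == "nonremoved_leaf"),
       W = ev$time[sel & ev$kind == "removed_leaf"],
       X = ev$time[sel & ev$kind == "branching"],
       Y = ev$time[sel & ev$kind == "nonremoved_leaf"],
       hasUnknown = any(sel & ev$kind %in%
                          c("unknown_leaf", "unknown_occurrence")),
       hasOccurrence = any(sel & ev$kind %in%
                             c("removed_occurrence",
                               "nonremoved_occurrence",
                               "unknown_occurrence")))
}

## 0 * log(0) = 0 convention for the rate-power factors
powLog <- function(count, rate) {
  if (count == 0) 0 else count * log(rate)
}

#' Closed-form backward vector without occurrence sampling
#'
#' When `omega = 0` (and the occurrence record is empty) the backward
#' vector factorizes as `L_t(i) = u_t^i W_t`, with `W_t` the product of
#' the event rate factors and ratios of `p` at the event times below `t`:
#' `W_t = lambda^x psi^(v+w+y) (1-r)^(v+y) r^w p_t^(k_t)
#'        prod_X p_tj prod_Y u_tj / p_tj prod_W 1 / p_tj`.
#'
#' @param schedule an [EventSchedule-class] (no occurrences).
#' @param params a [BDParams-class] with `omega = 0`.
#' @param t evaluation time (events exactly at `t` are not counted,
#'   matching the present-side recording convention of [computeL()]).
#' @param iMax largest hidden count to evaluate.
#' @return a [ProbVector-class] at time `t`.
#' @export
closedFormLNoOmega <- function(schedule, params, t, iMax) {
  if (params@omega > 0) stop("closed form requires omega = 0")
  cts <- eventCounts(schedule, lower = -Inf, upper = t)
  if (cts$hasOccurrence) stop("closed form requires an empty occurrence record")
  if (cts$hasUnknown) stop("closed form requires labeled removal statuses")
  ev <- schedule@events
  row <- max(which(ev$time <= t))
  ## on a schedule time, use the present side (t-); inside an epoch, its k
  kt <- if (t == ev$time[row]) kBelowRow(schedule)[row]
        else schedule@kEpoch[row]
  pt <- function(s) probSingleSample(s, params)
  logW <- powLog(cts$x, params@lambda) +
    powLog(cts$v + cts$w + cts$y, params@psi) +
    powLog(cts$v + cts$y, 1 - params@r) +
    powLog(cts$w, params@r) +
    kt * log(pt(t)) +
    sum(log(pt(cts$X))) +
    sum(log(probNoSample(cts$Y, params)) - log(pt(cts$Y))) -
    sum(log(pt(cts$W)))
  ut <- probNoSample(t, params)
  newProbVector(exp((0:iMax) * log(ut)), logScale = logW,
                k = as.integer(kt), t = t)
}

#' Closed-form density of a reconstructed tree (no occurrences)
#'
#' When `omega = 0` the joint density reduces to the classical
#' sampled-ancestor birth-death tree density
#' `P(T) = lambda^(w+y+k0-1) psi^(v+w+y) (1-r)^(v+y) r^w
#'         prod_(X U {tOr}) p_tj prod_Y u_tj/p_tj prod_W 1/p_tj`,
#' with `v` sampled ancestors, `w` removed leaves (times `W`), `y`
#' non-removed leaves (times `Y`) and branching times `X`.  At `r = 0`
#' removed leaves are impossible (`r^w = 0`) and the formula reduces to
#' the classical fossilized birth-death shape.
#'
#' @param schedule an [EventSchedule-class] built with `omega = 0` data.
#' @param params a [BDParams-class] with `omega = 0`.
#' @return the log density of the tree.
#' @export
fbdTreeDensity <- function(schedule, params) {
  if (params@omega > 0) stop("closed form requires omega = 0")
  cts <- eventCounts(schedule)
  if (cts$hasOccurrence) stop("closed form requires an empty occurrence record")
  if (cts$hasUnknown) stop("closed form requires labeled removal statuses")
  k0 <- schedule@k0
  stopifnot(cts$x == cts$w + cts$y + k0 - 1L)
  pt <- function(s) probSingleSample(s, params)
  powLog(cts$x, params@lambda) +
    powLog(cts$v + cts$w + cts$y, params@psi) +
    powLog(cts$v + cts$y, 1 - params@r) +
    powLog(cts$w, params@r) +
    sum(log(pt(c(cts$X, params@tOr)))) +
    sum(log(probNoSample(cts$Y, params)) - log(pt(cts$Y))) -
    sum(log(pt(cts$W)))
}
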
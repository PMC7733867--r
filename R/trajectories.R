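## Conditioned population-size trajectories.
##
## Trajectories are drawn in calendar-forward direction (origin to
## present, t decreasing) with the L-based Doob rates, because the initial
## state there is deterministic (one individual, no hidden ones).  The
## rates are inhomogeneous through L_t; L is computed on a fine grid and
## interpolated log-linearly inside each step, and jumps are drawn by
## thinning: exp of a linear interpolant is convex, so the larger of the
## two endpoint rates is a valid envelope on the whole step.

## insert extra (grid) times into an existing schedule
scheduleWithGrid <- function(schedule, times) {
  ev <- schedule@events
  times <- sort(unique(times))
  stopifnot(all(times >= 0 & times <= schedule@tOr))
  ev$grid <- ev$grid | ev$time %in% times
  extra <- setdiff(times, ev$time)
  if (length(extra)) {
    ins <- data.frame(time = extra, kind = "grid", grid = TRUE,
                      stringsAsFactors = FALSE)
    ev2 <- rbind(ev, ins)
    ord <- order(ev2$time)
    ev2 <- ev2[ord, , drop = FALSE]
    ## splitting an epoch copies its lineage count
    kOld <- schedule@kEpoch
    pos <- findInterval(ev2$time[-1L], ev$time, left.open = TRUE)
    kNew <- kOld[pmin(pos, length(kOld))]
    return(new("EventSchedule", events = ev2, kEpoch = as.integer(kNew),
               k0 = schedule@k0, tOr = schedule@tOr))
  }
  new("EventSchedule", events = ev, kEpoch = schedule@kEpoch,
      k0 = schedule@k0, tOr = schedule@tOr)
}

## calendar-forward deterministic hidden-count shift when crossing an event
## from above to below (total population size is continuous except where
## an individual is born or removed)
eventShiftDown <- c(removed_leaf = 0L, nonremoved_leaf = +1L,
                    unknown_leaf = 0L, sampled_ancestor = 0L,
                    removed_occurrence = -1L, nonremoved_occurrence = 0L,
                    unknown_occurrence = 0L, branching = 0L,
                    grid = 0L, present = 0L)

#' Sample conditioned population-size trajectories
#'
#' Draws piecewise-constant trajectories of the total population size
#' `I(t) = k_t + i(t)` on `[0, tOr]`, conditioned on the data, by
#' simulating the hidden count `i` as an inhomogeneous Markov jump process
#' with the L-based Doob rates ([doobRates()]), starting at the origin
#' with `I = 1`, `i = 0`.  At data events the hidden count shifts
#' deterministically: crossing a non-removed leaf (downwards in time) the
#' sampled lineage ends and its individual joins the hidden pool
#' (`i -> i + 1`, `k -> k - 1`); crossing a removed occurrence the sampled
#' hidden individual is removed (`i -> i - 1`); all other events leave `i`
#' unchanged.  Unknown-status leaves and occurrences are treated as
#' non-shifting only insofar as their labels say: for `unknown_leaf` the
#' shift is drawn from the posterior odds of the two labels at the current
#' state; `unknown_occurrence` likewise.
#'
#' A trajectory that reaches a state of zero backward probability (a
#' truncation/underflow artefact, or `i = 0` at a removed occurrence) is
#' restarted; the fraction of restarts is reported and should be
#' negligible on an adequately fine grid.
#'
#' @param schedule an [EventSchedule-class].
#' @param params a [BDParams-class].
#' @param N truncation of the hidden-individual count.
#' @param nTraj number of trajectories.
#' @param recordTimes times at which the states are returned (default: the
#'   schedule's grid times).
#' @param stepFrac maximum interpolation step, as a fraction of `tOr`.
#' @return a list with `times` (the record times, ascending), `I`
#'   (matrix `nTraj` x `length(times)` of total counts, recorded on the
#'   present side of each time), `k` (lineage counts at the record times)
#'   and `resampleRate`.
#' @export
sampleTrajectories <- function(schedule, params, N, nTraj,
                               recordTimes = NULL, stepFrac = 0.01) {
  ev0 <- schedule@events
  if (is.null(recordTimes)) recordTimes <- ev0$time[ev0$grid]
  if (!length(recordTimes)) stop("no record times")
  fine <- sort(unique(c(ev0$time, recordTimes,
                        seq(0, schedule@tOr, by = stepFrac * schedule@tOr))))
  fs <- scheduleWithGrid(schedule, fine)
  Ls <- computeL(fs, params, N, checkTail = FALSE)
  if (!is.finite(Ls$logDensity))
    stop("cannot sample trajectories: the data have zero density")
  ev <- fs@events
  m <- nrow(ev)
  kBelow <- kBelowRow(fs)
  ## log L on both sides of every row (upper side = after backward update)
  logLminus <- lapply(Ls$vectors, function(pv) log(pv@values))
  logLplus <- logLminus
  dataKind <- !(ev$kind %in% c("grid", "present", "origin"))
  for (h in seq_len(m)) {
    if (dataKind[h])
      logLplus[[h]] <- log(updateLEvent(Ls$vectors[[h]], ev$kind[h],
                                        params)@values)
  }
  psi <- params@psi; omega <- params@omega; r <- params@r

  recIdx <- match(sort(unique(recordTimes)), ev$time)
  recTimes <- ev$time[recIdx]
  I <- matrix(NA_integer_, nTraj, length(recIdx))
  resamples <- 0L

  for (tr in seq_len(nTraj)) {
    repeat {
      ok <- TRUE
      i <- 0L
      rec <- integer(length(recIdx))
      if (m %in% recIdx) rec[match(m, recIdx)] <- 1L   # I(tOr) = 1
      for (h in m:2L) {
        tHi <- ev$time[h]; tLo <- ev$time[h - 1L]
        k <- fs@kEpoch[h - 1L]
        ## inside the open interval, L is continuous: its limits are the
        ## below-side value at the top row and the above-side value at the
        ## bottom row
        lhi <- logLminus[[h]]; llo <- logLplus[[h - 1L]]
        s <- tHi
        span <- tHi - tLo
        repeat {
          if (!is.finite(lhi[i + 1L]) || !is.finite(llo[i + 1L])) {
            ok <- FALSE; break
          }
          upHi <- if (i < N) params@lambda * (2 * k + i) *
            exp(lhi[i + 2L] - lhi[i + 1L]) else 0
          upLo <- if (i < N) params@lambda * (2 * k + i) *
            exp(llo[i + 2L] - llo[i + 1L]) else 0
          dnHi <- if (i > 0L) params@mu * i *
            exp(lhi[i] - lhi[i + 1L]) else 0
          dnLo <- if (i > 0L) params@mu * i *
            exp(llo[i] - llo[i + 1L]) else 0
          bound <- max(upHi, upLo) + max(dnHi, dnLo)
          if (bound <= 0) break
          s2 <- s - stats::rexp(1L, bound)
          if (s2 <= tLo) break
          th <- (s2 - tLo) / span
          up <- if (i < N) params@lambda * (2 * k + i) *
            exp(th * (lhi[i + 2L] - lhi[i + 1L]) +
                  (1 - th) * (llo[i + 2L] - llo[i + 1L])) else 0
          dn <- if (i > 0L) params@mu * i *
            exp(th * (lhi[i] - lhi[i + 1L]) +
                  (1 - th) * (llo[i] - llo[i + 1L])) else 0
          if (stats::runif(1L) * bound < up + dn) {
            i <- if (stats::runif(1L) * (up + dn) < up) i + 1L else i - 1L
          }
          s <- s2
        }
        if (!ok) break
        ## cross the event at tLo (from above to below)
        kind <- ev$kind[h - 1L]
        if (dataKind[h - 1L]) {
          shift <- eventShiftDown[[kind]]
          if (kind == "unknown_leaf") {
            ## posterior odds of (removed : non-removed) leaf labels
            wRem <- psi * r * exp(logLminus[[h - 1L]][i + 1L])
            wNon <- if (i < N) psi * (1 - r) *
              exp(logLminus[[h - 1L]][i + 2L]) else 0
            shift <- if (stats::runif(1L) * (wRem + wNon) < wRem) 0L else 1L
          } else if (kind == "unknown_occurrence") {
            wRem <- if (i > 0L) omega * r * i *
              exp(logLminus[[h - 1L]][i]) else 0
            wNon <- omega * (1 - r) * (k + i) *
              exp(logLminus[[h - 1L]][i + 1L])
            shift <- if (stats::runif(1L) * (wRem + wNon) < wRem) -1L else 0L
          }
          i <- i + shift
          if (i < 0L || i > N) { ok <- FALSE; break }
        }
        if ((h - 1L) %in% recIdx)
          rec[match(h - 1L, recIdx)] <- kBelow[h - 1L] + i
      }
      if (ok) { I[tr, ] <- rec; break }
      resamples <- resamples + 1L
      if (resamples > 100L * nTraj)
        stop("trajectory sampling keeps hitting zero-probability states; ",
             "increase N or refine the grid")
    }
  }
  rate <- resamples / (resamples + nTraj)
  if (rate > 0.01)
    warning(sprintf(paste0("%.1f%% of trajectories were resampled; the ",
                           "interpolation grid may be too coarse"),
                    100 * rate), call. = FALSE)
  list(times = recTimes, I = I, k = kBelow[recIdx], resampleRate = rate)
}
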
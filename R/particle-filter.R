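## Bootstrap particle filter for the conditioned population size: the
## independent Monte-Carlo cross-check of the analytic traversals.
##
## Particles carry the hidden count i and move calendar-forward (origin to
## present).  Within an epoch they follow the unconditioned hidden
## dynamics (up-rate lambda (2k + i), down-rate mu i, the off-diagonal
## structure of the backward master equation) and accumulate the survival
## weight exp(-integral c(i) dt) with c(i) = (mu - lambda) k +
## (psi + omega)(k + i), the rate of events that would have contradicted
## the data (an unobserved sampling, or a death/unsampled fate on an
## observed lineage).  At every data event the particles are reweighted by
## the event's rate factor and shifted like the conditioned trajectories.
##
## The reported marginals are smoothing marginals (conditioned on ALL the
## data, like the analytic posterior): every particle drags its ancestral
## history of recorded states through the resampling steps, and the
## histories are weighted at the very end (a genealogy filter-smoother).
## Path degeneracy makes the Monte-Carlo error grow towards the origin;
## the effective history size is reported per time.

systematicResample <- function(lw, n = length(lw)) {
  w <- exp(lw - max(lw))
  w <- w / sum(w)
  u <- (stats::runif(1L) + 0:(n - 1L)) / n
  findInterval(u, cumsum(w)) + 1L
}

#' Particle-filter posterior of the past population size
#'
#' Runs a bootstrap filter with systematic resampling over the event
#' schedule and returns genealogy-smoothed marginals of the hidden count
#' at every grid time (on the present side of coincident events, like
#' [computeK()]).  The filter shares no code with the analytic traversals
#' and serves as their Monte-Carlo oracle; its log marginal-likelihood
#' estimate targets `log P(T, O)`.
#'
#' @param schedule an [EventSchedule-class].
#' @param params a [BDParams-class].
#' @param nParticles number of particles (>= 1000 recommended).
#' @param maxI truncation of the reported marginal support (particles
#'   themselves are unbounded).
#' @param essFrac resample at grid times when the effective sample size
#'   drops below `essFrac * nParticles` (data events always resample).
#' @return list with `posterior` (a [PosteriorGrid-class] whose
#'   `logDensity` is the filter's log marginal likelihood), `logMarginal`
#'   and `stateESS` (effective number of distinct recorded states
#'   per time, a path-degeneracy diagnostic).
#' @export
particleFilterPosterior <- function(schedule, params, nParticles = 1e4,
                                    maxI = 100L, essFrac = 0.5) {
  ev <- schedule@events
  kEp <- schedule@kEpoch
  m <- nrow(ev)
  lambda <- params@lambda; mu <- params@mu
  psi <- params@psi; omega <- params@omega
  r <- params@r; rho <- params@rho
  i <- integer(nParticles)          # hidden counts, at the origin all 0
  lw <- numeric(nParticles)
  logML <- 0
  gridRows <- which(ev$grid)
  H <- matrix(NA_integer_, nParticles, length(gridRows))

  record <- function(h) {
    H[, match(h, gridRows)] <<- i
  }
  fold <- function() {              # fold current weights into the ML
    logML <<- logML + logSumExp(lw) - log(nParticles)
    idx <- systematicResample(lw)
    i <<- i[idx]
    H <<- H[idx, , drop = FALSE]
    lw <<- numeric(nParticles)
  }

  if (ev$grid[m]) record(m)
  for (h in (m - 1L):1L) {
    k <- kEp[h]
    dt <- ev$time[h + 1L] - ev$time[h]
    if (dt > 0) {
      ## vectorized exact jump simulation over the epoch, with the
      ## survival weight integrated along each piecewise-constant path
      tRem <- rep(dt, nParticles)
      active <- rep(TRUE, nParticles)
      while (any(active)) {
        ia <- i[active]
        rate <- lambda * (2 * k + ia) + mu * ia
        tau <- ifelse(rate > 0,
                      stats::rexp(sum(active), pmax(rate, 1e-300)), Inf)
        hold <- pmin(tau, tRem[active])
        lw[active] <- lw[active] -
          ((mu - lambda) * k + (psi + omega) * (k + ia)) * hold
        jump <- tau < tRem[active]
        if (any(jump)) {
          iaj <- ia[jump]
          goUp <- stats::runif(sum(jump)) * (lambda * (2 * k + iaj) +
                                               mu * iaj) <
            lambda * (2 * k + iaj)
          ii <- which(active)[jump]
          i[ii] <- iaj + ifelse(goUp, 1L, -1L)
          tRem[ii] <- tRem[ii] - tau[jump]
        }
        active[which(active)[!jump]] <- FALSE
      }
    }
    kind <- ev$kind[h]
    if (kind == "present") {
      lw <- lw + schedule@k0 * log(rho) + i * log1p(-rho)
      if (ev$grid[h]) record(h)
      logML <- logML + logSumExp(lw) - log(nParticles)
      break
    }
    if (!kind %in% c("grid", "origin")) {
      if (kind == "removed_leaf") {
        lw <- lw + log(psi * r)
      } else if (kind == "nonremoved_leaf") {
        lw <- lw + log(psi * (1 - r)); i <- i + 1L
      } else if (kind == "unknown_leaf") {
        lw <- lw + log(psi)
        i <- i + (stats::runif(nParticles) > r)     # non-removed branch
      } else if (kind == "sampled_ancestor") {
        lw <- lw + log(psi * (1 - r))
      } else if (kind == "removed_occurrence") {
        lw <- lw + ifelse(i > 0L, log(omega * r * i), -Inf)
        i <- pmax(i - 1L, 0L)
      } else if (kind == "nonremoved_occurrence") {
        lw <- lw + log(omega * (1 - r) * (k + i))
      } else if (kind == "unknown_occurrence") {
        wRem <- omega * r * i
        wNon <- omega * (1 - r) * (k + i)
        pick <- stats::runif(nParticles) * (wRem + wNon) < wRem
        lw <- lw + log(wRem + wNon)
        i <- i - pick
      } else if (kind == "branching") {
        lw <- lw + log(lambda)
      }
      if (all(!is.finite(lw)))
        stop("particle filter collapsed: all weights are zero")
      fold()
    }
    if (ev$grid[h]) {
      record(h)
      w <- exp(lw - max(lw))
      if (sum(w)^2 / sum(w^2) < essFrac * nParticles) fold()
    }
  }
  ## final weights apply to the whole surviving histories
  w <- exp(lw - max(lw)); w <- w / sum(w)
  recT <- ev$time[gridRows]
  probs <- t(vapply(seq_along(gridRows), function(j) {
    p <- vapply(0:maxI, function(v) sum(w[H[, j] == v]), numeric(1))
    p / sum(p)
  }, numeric(maxI + 1L)))
  stateESS <- vapply(seq_along(gridRows), function(j) {
    ag <- rowsum(w, H[, j])
    1 / sum(ag^2)
  }, numeric(1))
  ord <- order(recT)
  post <- new("PosteriorGrid", times = recT[ord],
              k = kBelowRow(schedule)[gridRows][ord],
              probs = probs[ord, , drop = FALSE],
              logDensity = logML, logDensityDrift = NA_real_)
  list(posterior = post, logMarginal = logML, stateESS = stateESS[ord])
}
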
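## Exact forward simulation of the full process.  Gillespie on the
## population-level aggregate rate gamma * I with a uniform choice of the
## affected individual; removal upon psi-/omega-sampling with probability
## r; independent Bernoulli(rho) sampling of the survivors at the present.

#' Simulate the full birth-death sampling process
#'
#' Runs the process from one individual at the origin down to the present
#' and returns the complete event log, the true population-size
#' trajectory, the reconstructed data (tree + occurrence record) and the
#' rho-sampling outcome.
#'
#' @param params a [BDParams-class].
#' @param seed optional integer seed.
#' @param requireObservation when TRUE, rejection-sample until the outcome
#'   carries at least one psi-, omega- or rho-sample (the empirical
#'   counterpart of conditioning the density on sampling).
#' @param requireTree when TRUE, additionally require at least one sample
#'   in the reconstructed tree (psi or rho), so that the tree is
#'   non-empty.
#' @param maxPop abort threshold for runaway populations.
#' @return a [SimOutcome-class].
#' @examples
#' p <- bdParams(1, 0.5, psi = 0.3, omega = 0.6, rho = 0.5, r = 0.2, tOr = 2)
#' sim <- simulateProcess(p, seed = 1, requireTree = TRUE)
#' sim
#' @export
simulateProcess <- function(params, seed = NULL, requireObservation = FALSE,
                            requireTree = FALSE, maxPop = 1e5) {
  if (!is.null(seed)) set.seed(seed)
  lambda <- params@lambda; mu <- params@mu
  psi <- params@psi; omega <- params@omega
  gamma <- params@gamma; r <- params@r; rho <- params@rho
  repeat {
    alive <- 1L
    nextId <- 1L
    evTime <- numeric(); evType <- character(); evId <- integer()
    evChild <- integer(); evRem <- logical()
    trTime <- params@tOr; trI <- 1L
    s <- params@tOr
    repeat {
      n <- length(alive)
      if (n == 0L) break
      if (n > maxPop)
        stop("population exceeded maxPop = ", maxPop,
             "; lower tOr or the net growth rate")
      s <- s - stats::rexp(1L, gamma * n)
      if (s <= 0) break
      type <- sample(c("birth", "death", "psi", "omega"), 1L,
                     prob = c(lambda, mu, psi, omega))
      who <- alive[sample.int(n, 1L)]
      removed <- NA
      child <- NA_integer_
      if (type == "birth") {
        nextId <- nextId + 1L
        child <- nextId
        alive <- c(alive, child)
      } else if (type == "death") {
        alive <- alive[alive != who]
      } else {
        removed <- stats::runif(1L) < r
        if (removed) alive <- alive[alive != who]
      }
      evTime <- c(evTime, s); evType <- c(evType, type)
      evId <- c(evId, who); evChild <- c(evChild, child)
      evRem <- c(evRem, removed)
      if (length(alive) != utils::tail(trI, 1L)) {
        trTime <- c(trTime, s); trI <- c(trI, length(alive))
      }
    }
    rhoSampled <- alive[stats::runif(length(alive)) < rho]
    events <- data.frame(time = evTime, type = evType, id = evId,
                         child = evChild, removed = evRem,
                         stringsAsFactors = FALSE)
    anyTreeSample <- any(evType == "psi") || length(rhoSampled) > 0L
    anySample <- anyTreeSample || any(evType == "omega")
    if ((requireTree && !anyTreeSample) ||
        (requireObservation && !anySample)) next
    break
  }
  recon <- reconstructData(events, rhoSampled, params)
  new("SimOutcome",
      events = events,
      trajectory = data.frame(time = c(trTime, 0),
                              I = c(trI, utils::tail(trI, 1L))),
      rhoSampled = as.integer(rhoSampled),
      tree = recon$tree, occurrences = recon$occurrences,
      params = params,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' True population size at given times
#'
#' Reads the piecewise-constant simulated trajectory at arbitrary times
#' (on the present side of any jump).
#'
#' @param sim a [SimOutcome-class].
#' @param times times before present.
#' @return integer population sizes.
#' @export
trueTrajectory <- function(sim, times) {
  tr <- sim@trajectory
  ## tr$time is descending from tOr; jumps take effect below their time
  vapply(times, function(tt) {
    tr$I[max(which(tr$time >= tt - 1e-12))]
  }, numeric(1))
}
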
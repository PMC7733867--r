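## Combining the two traversals: K_t(i) = P(I_t = k_t + i | T, O)
## is proportional to L_t(i) M_t(i); the proportionality constant is the
## joint density P(T, O) at every time, which doubles as the sharpest
## full-pipeline diagnostic.

#' Posterior distribution of the past population size
#'
#' Combines the recorded backward and forward vectors into the posterior
#' `K_tau(i) = L_tau(i) M_tau(i) / P(T, O)` at every grid time.  The
#' pre-normalization row sums are all estimates of `P(T, O)`; their
#' largest relative spread is reported as `logDensityDrift` and is a
#' direct measure of truncation adequacy.
#'
#' @param Ls result of [computeL()].
#' @param Ms result of [computeM()] on the same schedule, truncation and
#'   grid.
#' @return a [PosteriorGrid-class].
#' @examples
#' p <- bdParams(1, 0.5, psi = 0.3, rho = 0.5, r = 0.2, tOr = 3)
#' tr <- readReconTree("((A:1,B:1):1);")
#' sched <- buildSchedule(tr, params = p, gridTimes = seq(0, 3, 0.5))
#' K <- computeK(computeL(sched, p, N = 40), computeM(sched, p, N = 40))
#' posteriorQuantiles(K, c(0.2, 0.5, 0.8))
#' @export
computeK <- function(Ls, Ms) {
  stopifnot(isTRUE(all.equal(Ls$gridTimes, Ms$gridTimes)))
  S <- length(Ls$gridTimes)
  if (S == 0L) stop("no grid times were recorded")
  N <- length(Ls$vectors[[1L]]@values) - 1L
  probs <- matrix(0, S, N + 1L)
  kk <- integer(S)
  logC <- numeric(S)
  for (j in seq_len(S)) {
    Lv <- Ls$vectors[[j]]; Mv <- Ms$vectors[[j]]
    stopifnot(length(Mv@values) == N + 1L)
    w <- Lv@values * Mv@values
    tot <- sum(w)
    if (tot == 0)
      stop("impossible data: zero posterior row at t = ", Lv@t)
    probs[j, ] <- w / tot
    logC[j] <- log(tot) + Lv@logScale + Mv@logScale
    kk[j] <- Lv@k
  }
  ld <- stats::median(logC)
  new("PosteriorGrid", times = Ls$gridTimes, k = kk, probs = probs,
      logDensity = ld,
      logDensityDrift = max(abs(expm1(logC - ld))))
}

#' Posterior population size for a tree plus occurrence record
#'
#' One-call wrapper: builds the schedule, runs both traversals and
#' combines them.
#'
#' @param tree a [ReconTree-class].
#' @param occ an [OccurrenceRecord-class].
#' @param params a [BDParams-class].
#' @param gridTimes evaluation times in `[0, tOr]`.
#' @param N truncation of the hidden-individual count.
#' @return a [PosteriorGrid-class].
#' @export
posteriorPopSize <- function(tree, occ = occurrenceRecord(), params,
                             gridTimes, N) {
  sched <- buildSchedule(tree, occ, params, gridTimes)
  computeK(computeL(sched, params, N), computeM(sched, params, N))
}

#' Posterior quantiles of the total population size
#'
#' Lower-quantile convention: the reported quantile at level `p` is the
#' smallest total count `n = k_tau + i` whose cumulative posterior
#' probability reaches `p`.
#'
#' @param K a [PosteriorGrid-class].
#' @param probs quantile levels.
#' @return data.frame with column `time`, `k`, and one column per level.
#' @export
posteriorQuantiles <- function(K, probs = c(0.2, 0.5, 0.8)) {
  out <- data.frame(time = K@times, k = K@k)
  qm <- t(vapply(seq_along(K@times), function(j) {
    support <- K@k[j] + 0:(ncol(K@probs) - 1L)
    vapply(probs, function(p) lowerQuantile(support, K@probs[j, ], p),
           numeric(1))
  }, numeric(length(probs))))
  colnames(qm) <- paste0("q", probs)
  cbind(out, qm)
}

#' Conditioned jump rates (Doob h-transform)
#'
#' The hidden-count process conditioned on the data is a Markov jump
#' process whose rates are the unconditioned hidden birth/death rates
#' tilted by the ratio of the conditioning vector at neighbouring states.
#' With the backward vector L (`basis = "L"`), in calendar-forward time
#' (t decreasing) the rates from hidden state j are
#' `up = lambda (2k + j) L(j+1) / L(j)` and `down = mu j L(j-1) / L(j)`.
#' With the forward vector M (`basis = "M"`), in past-ward time
#' (t increasing) they are `up = mu (j+1) M(j+1) / M(j)` and
#' `down = lambda (2k + j - 1) M(j-1) / M(j)` (zero at j = 0).
#'
#' @param pv a [ProbVector-class] (an L or M row; its `k` slot is used).
#' @param params a [BDParams-class].
#' @param basis `"L"` (calendar-forward) or `"M"` (past-ward).
#' @return list of numeric vectors `up` and `down` over j = 0..N.  A
#'   division by a zero entry inside the reachable support yields `NaN`
#'   or `Inf`, signalling truncation/underflow failure to the caller.
#' @export
doobRates <- function(pv, params, basis = c("L", "M")) {
  basis <- match.arg(basis)
  v <- pv@values
  N <- length(v) - 1L
  j <- 0:N
  k <- pv@k
  if (basis == "L") {
    up <- params@lambda * (2 * k + j) * c(v[-1L], 0) / v
    down <- params@mu * j * c(1, v[-(N + 1L)]) / v   # j = 0 term is 0
    down[1L] <- 0
  } else {
    up <- params@mu * (j + 1) * c(v[-1L], 0) / v
    down <- params@lambda * (2 * k + j - 1) * c(1, v[-(N + 1L)]) / v
    down[1L] <- 0
  }
  list(up = up, down = down)
}
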
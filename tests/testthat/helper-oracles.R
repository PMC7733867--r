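## Independent numerical oracles used by the tests.  All adaptive-ODE
## integration lives here, never in the package code paths it checks.

## u and p by adaptive integration of their defining ODEs
odeUP <- function(t, z, params) {
  f <- function(s, y, parms) {
    list(c(params@lambda * y[1]^2 - params@gamma * y[1] + params@mu,
           (2 * params@lambda * y[1] - params@gamma) * y[2]))
  }
  out <- deSolve::ode(c(u = z, p = 1 - z), c(0, t), f, NULL,
                      method = "lsoda", rtol = 1e-12, atol = 1e-14)
  out[nrow(out), c("u", "p")]
}

## truncated backward master equation, integrated adaptively
odeEvolveL <- function(values, k, dt, params) {
  N <- length(values) - 1L
  i <- 0:N
  f <- function(s, y, parms) {
    list(-params@gamma * (k + i) * y +
           params@lambda * (2 * k + i) * c(y[-1L], 0) +
           params@mu * i * c(0, y[-(N + 1L)]))
  }
  out <- deSolve::ode(values, c(0, dt), f, NULL, method = "lsoda",
                      rtol = 1e-12, atol = 1e-16)
  out[nrow(out), -1L]
}

## truncated forward master equation in s = tTop - t (downward time)
odeEvolveM <- function(values, k, dt, params) {
  N <- length(values) - 1L
  i <- 0:N
  f <- function(s, y, parms) {
    list(-params@gamma * (i + k) * y +
           params@lambda * (2 * k + i - 1) * c(0, y[-(N + 1L)]) +
           params@mu * (i + 1) * c(y[-1L], 0))
  }
  out <- deSolve::ode(values, c(0, dt), f, NULL, method = "lsoda",
                      rtol = 1e-12, atol = 1e-16)
  out[nrow(out), -1L]
}

randomParams <- function(tOr = 5) {
  bdParams(lambda = runif(1, 0.5, 2), mu = runif(1, 0.1, 1.5),
           psi = runif(1, 0.05, 0.6), omega = runif(1, 0.05, 0.8),
           rho = runif(1, 0.05, 0.95), r = runif(1, 0, 1), tOr = tOr)
}

pv <- function(values, k = 1L, t = 0) {
  new("ProbVector", values = values, logScale = 0, k = as.integer(k), t = t)
}

tvDist <- function(p, q) 0.5 * sum(abs(p - q))

## lineages-through-time read directly off the node table (independent of
## the schedule sweep): one edge per non-root node, plus the root stem
lttFromTree <- function(tree, tOr, t) {
  nd <- treeNodes(tree)
  lo <- nd$age
  hi <- ifelse(is.na(nd$parent), tOr, nd$age[match(nd$parent, nd$id)])
  sum(lo <= t & t < hi)
}

## empirical marginal of trajectory states against a posterior row
empiricalTV <- function(tra, K, j) {
  N <- ncol(posteriorMatrix(K)) - 1L
  emp <- tabulate(tra$I[, j] - tra$k[j] + 1L, nbins = N + 1L) / nrow(tra$I)
  tvDist(emp, posteriorMatrix(K)[j, ])
}

## The past-ward (M-based) Doob sampler, used only to confirm that both
## rate parameterizations reproduce the same marginals.  States start from
## the posterior at the present and move towards the origin with rates
## up = mu (j+1) M(j+1)/M(j), down = lambda (2k+j-1) M(j-1)/M(j); crossing
## an event upward inverts the calendar-forward deterministic shifts.
sampleTrajBackwardM <- function(schedule, params, N, nTraj,
                                recordTimes, stepFrac = 0.01) {
  ev0 <- scheduleEvents(schedule)
  fine <- sort(unique(c(ev0$time, recordTimes,
                        seq(0, schedule@tOr, by = stepFrac * schedule@tOr))))
  fs <- occupop:::scheduleWithGrid(schedule, fine)
  ev <- scheduleEvents(fs)
  m <- nrow(ev)
  kEp <- lineageCounts(fs)
  ## manual forward sweep recording both sides of every row
  Mplus <- Mminus <- vector("list", m)
  M <- initM(N, tOr = fs@tOr)
  Mplus[[m]] <- Mminus[[m]] <- M
  for (h in (m - 1L):1L) {
    M@k <- kEp[h]
    M <- evolveMEpoch(M, ev$time[h + 1L] - ev$time[h], params)
    Mplus[[h]] <- M
    if (!ev$kind[h] %in% c("grid", "origin"))
      M <- updateMEvent(M, if (ev$kind[h] == "present") "present"
                        else ev$kind[h], params)
    Mminus[[h]] <- M
  }
  ## initial states from the posterior at the present
  Ls <- computeL(fs, params, N, checkTail = FALSE)
  K0 <- Ls$vectors[[1L]]@values * Mplus[[1L]]@values
  K0 <- K0 / sum(K0)
  lM <- lapply(Mminus, function(x) log(x@values))
  lMp <- lapply(Mplus, function(x) log(x@values))
  kBel <- occupop:::kBelowRow(fs)
  recIdx <- match(sort(unique(recordTimes)), ev$time)
  I <- matrix(NA_integer_, nTraj, length(recIdx))
  lambda <- params@lambda; mu <- params@mu
  for (tr in seq_len(nTraj)) {
   repeat {                     # restart on zero-probability states
    ok <- TRUE
    i <- sample.int(N + 1L, 1L, prob = K0) - 1L
    if (1L %in% recIdx) I[tr, match(1L, recIdx)] <- kBel[1L] + i
    for (h in 2:m) {
      tLo <- ev$time[h - 1L]; tHi <- ev$time[h]
      k <- kEp[h - 1L]
      llo <- lMp[[h - 1L]]; lhi <- lM[[h]]
      s <- tLo; span <- tHi - tLo
      rr <- function(lv, from, to, fac)                 # tilted rate, 0 off-support
        if (to < 0L || to > N || !is.finite(lv[to + 1L])) 0
        else fac * exp(lv[to + 1L] - lv[from + 1L])
      repeat {
        if (!is.finite(lhi[i + 1L]) || !is.finite(llo[i + 1L])) {
          ok <- FALSE; break
        }
        upHi <- rr(lhi, i, i + 1L, mu * (i + 1))
        upLo <- rr(llo, i, i + 1L, mu * (i + 1))
        dnHi <- rr(lhi, i, i - 1L, lambda * (2 * k + i - 1))
        dnLo <- rr(llo, i, i - 1L, lambda * (2 * k + i - 1))
        bound <- max(upHi, upLo) + max(dnHi, dnLo)
        if (bound <= 0) break
        s2 <- s + rexp(1L, bound)
        if (s2 >= tHi) break
        th <- (s2 - tLo) / span
        up <- upHi^th * upLo^(1 - th)
        dn <- dnHi^th * dnLo^(1 - th)
        if (runif(1L) * bound < up + dn)
          i <- if (runif(1L) * (up + dn) < up) i + 1L else i - 1L
        s <- s2
      }
      ## record on the present side of the upper row, then cross upward
      if (h %in% recIdx) I[tr, match(h, recIdx)] <- kBel[h] + i
      kind <- ev$kind[h]
      if (!kind %in% c("grid", "origin", "present")) {
        wts <- NULL
        if (kind == "unknown_leaf") {
          wRem <- params@psi * params@r * exp(lMp[[h]][i + 1L])
          wNon <- if (i > 0L) params@psi * (1 - params@r) *
            exp(lMp[[h]][i]) else 0
          i <- i - (runif(1L) * (wRem + wNon) >= wRem)
        } else if (kind == "unknown_occurrence") {
          wRem <- if (i < N) params@omega * params@r * (i + 1) *
            exp(lMp[[h]][i + 2L]) else 0
          wNon <- params@omega * (1 - params@r) * (k + i) *
            exp(lMp[[h]][i + 1L])
          i <- i + (runif(1L) * (wRem + wNon) < wRem)
        } else {
          i <- i - occupop:::eventShiftDown[[kind]]
        }
        if (i < 0L || i > N) { ok <- FALSE }
      }
      if (!ok) break
    }
    if (ok) break
   }
  }
  list(times = ev$time[recIdx], I = I, k = kBel[recIdx])
}
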
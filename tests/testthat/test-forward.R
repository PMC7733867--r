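test_that("the forward initial vector is a point mass at the origin", {
  M <- initM(5, tOr = 4)
  expect_equal(probValues(M), c(1, 0, 0, 0, 0, 0))
  expect_equal(sum(probValues(M)), 1)
  expect_equal(M@k, 1L)
  expect_equal(M@t, 4)
})

test_that("the generating-function epoch solve matches the ODE oracle", {
  set.seed(21)
  q0 <- randomParams()
  v <- pv(c(0.3, 0.5, 0.2), 2L, t = 1)
  expect_equal(probValues(evolveMEpoch(v, 0, q0)), c(0.3, 0.5, 0.2))
  sup <- 0
  for (rep in 1:10) {
    q <- randomParams()
    N <- 40L
    k <- sample(1:4, 1)
    dt <- runif(1, 0.1, 0.7)
    ## steep tails keep the boundary flux (absent from both the analytic
    ## path and the truncated oracle in different ways) negligible
    v0 <- exp(-(0:N) * runif(1, 0.9, 1.4)) * runif(N + 1, 0.5, 1)
    got <- probValues(evolveMEpoch(pv(v0, k, t = dt), dt, q))
    want <- odeEvolveM(v0, k, dt, q)
    sup <- max(sup, max(abs(got - want)))
  }
  expect_lt(sup, 1e-7)
})

test_that("forward event updates mirror the backward ones", {
  p <- bdParams(1.5, 0.5, psi = 0.3, omega = 0.4, rho = 0.7, r = 0.2,
                tOr = 5)
  set.seed(4)
  v <- pv(runif(6), k = 3L)
  nl <- updateMEvent(v, "nonremoved_leaf", p)
  expect_equal(probValues(nl)[1], 0)
  expect_equal(nl@k, 2L)
  pr <- updateMEvent(pv(runif(6), k = 0L), "present",
                     bdParams(1, 0.5, rho = 1, tOr = 1))
  expect_equal(probValues(pr)[-1], rep(0, 5))
})

test_that("each event pair preserves the L-M inner product", {
  ## sum_i L+(i) M+(i) = sum_i L-(i) M-(i) for every event kind: the
  ## event factorization is exactly adjoint, even on the truncated space
  p <- bdParams(1.5, 0.5, psi = 0.3, omega = 0.4, rho = 0.7, r = 0.2,
                tOr = 5)
  set.seed(8)
  kinds <- c("removed_leaf", "nonremoved_leaf", "unknown_leaf",
             "sampled_ancestor", "removed_occurrence",
             "nonremoved_occurrence", "unknown_occurrence", "branching")
  for (kind in kinds) {
    kAbove <- 3L
    kBelow <- kAbove - occupop:::kindKStep[[kind]]
    Lbelow <- pv(runif(8), k = kBelow)
    Mabove <- pv(runif(8), k = kAbove)
    Labove <- updateLEvent(Lbelow, kind, p)
    Mbelow <- updateMEvent(Mabove, kind, p)
    expect_equal(Labove@k, kAbove)
    expect_equal(Mbelow@k, kBelow)
    expect_equal(sum(probValues(Labove) * probValues(Mabove)),
                 sum(probValues(Lbelow) * probValues(Mbelow)),
                 tolerance = 1e-12, label = kind)
  }
})

test_that("the trivial-tree forward density equals p(tOr, 1 - rho)", {
  p <- bdParams(1, 0.5, psi = 0.3, omega = 0.6, rho = 0.5, r = 0.2, tOr = 2)
  M <- initM(50, tOr = 2)
  M <- evolveMEpoch(M, 2, p)
  dens <- sum(p@rho^1 * (1 - p@rho)^(0:50) * M@values) * exp(M@logScale)
  expect_equal(log(dens), log(probSingleSample(2, p)), tolerance = 1e-10)
})

test_that("the no-occurrence closed-form recursion matches the sweep", {
  p <- bdParams(1.2, 1, psi = 0.3, omega = 0, rho = 0.5, r = 0.2, tOr = 3)
  ds <- makeDataset(p, seed = 11, gridTimes = c(0.8, 1.7, 2.5))
  Ms <- computeM(ds$sched, p, ds$N, checkTail = FALSE)
  for (j in seq_along(Ms$gridTimes)) {
    ref <- probValues(Ms$vectors[[j]])
    cf <- closedFormMNoOmega(ds$sched, p, Ms$gridTimes[j], ds$N)
    expect_lt(max(abs(probValues(cf) - ref)) / max(ref), 1e-6)
    expect_equal(cf@k, Ms$vectors[[j]]@k)
  }
  expect_error(closedFormMNoOmega(ds$sched, refParams(1.2), 1, 10), "omega")
})

test_that("the first-order coefficient matches a finite difference of M-hat", {
  ## M_t(1) = d/dz M-hat(t, z) at z = 0, with M-hat the closed product
  p <- bdParams(1.2, 1, psi = 0.3, omega = 0, rho = 0.5, r = 0.2, tOr = 3)
  ds <- makeDataset(p, seed = 11)
  ev <- scheduleEvents(ds$sched)
  t <- 1.23
  sel <- ev$time > t & ev$time < p@tOr
  X <- c(ev$time[sel & ev$kind == "branching"], p@tOr) - t
  W <- ev$time[sel & ev$kind == "removed_leaf"] - t
  Y <- ev$time[sel & ev$kind == "nonremoved_leaf"] - t
  v <- sum(sel & ev$kind == "sampled_ancestor")
  wct <- length(W); yct <- length(Y); xct <- length(X) - 1L
  Mhat <- function(z) {
    p@lambda^xct * p@psi^(v + wct + yct) * p@r^wct * (1 - p@r)^(v + yct) *
      prod(singleSampleRatio(X, p, z = z)) /
      prod(singleSampleRatio(W, p, z = z)) *
      prod(probNoSample(Y, p, z = z) / singleSampleRatio(Y, p, z = z))
  }
  cf <- closedFormMNoOmega(ds$sched, p, t, 3)
  h <- 1e-6
  expect_equal(probValues(cf)[2], (Mhat(h) - Mhat(0)) / h,
               tolerance = 1e-4)
  expect_equal(probValues(cf)[1], Mhat(0), tolerance = 1e-10)
})

test_that("without occurrences the density is rho^k0 M-hat(0+, 1 - rho)", {
  p <- bdParams(1.2, 1, psi = 0.3, omega = 0, rho = 0.5, r = 0.2, tOr = 3)
  ds <- makeDataset(p, seed = 11)
  ev <- scheduleEvents(ds$sched)
  sel <- ev$time > 0 & ev$time < p@tOr
  X <- c(ev$time[sel & ev$kind == "branching"], p@tOr)
  W <- ev$time[sel & ev$kind == "removed_leaf"]
  Y <- ev$time[sel & ev$kind == "nonremoved_leaf"]
  v <- sum(sel & ev$kind == "sampled_ancestor")
  z <- 1 - p@rho
  MhatAtPresent <- p@lambda^(length(X) - 1L) *
    p@psi^(v + length(W) + length(Y)) * p@r^length(W) *
    (1 - p@r)^(v + length(Y)) *
    prod(singleSampleRatio(X, p, z = z)) /
    prod(singleSampleRatio(W, p, z = z)) *
    prod(probNoSample(Y, p, z = z) / singleSampleRatio(Y, p, z = z))
  expect_equal(logDensityForward(ds$sched, p, ds$N),
               ds$sched@k0 * log(p@rho) + log(MhatAtPresent),
               tolerance = 1e-8)
})
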
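test_that("the backward initial vector is the rho-sampling law", {
  L <- initL(2, 0.5, 4)
  expect_equal(probValues(L)[1:3], c(0.25, 0.125, 0.0625))
  expect_equal(probValues(initL(3, 1, 4)), c(1, 0, 0, 0, 0))
  expect_equal(probValues(initL(0, 0.2, 5)), 0.8^(0:5))
  expect_error(initL(2, 0, 4), "impossible")
})

test_that("event updates follow the six punctual-event rules", {
  p <- bdParams(1.5, 0.5, psi = 0.3, omega = 0.4, rho = 0.5, r = 0.2,
                tOr = 5)
  set.seed(3)
  v <- pv(runif(6), k = 2L)
  ## removed occurrence: the i = 0 entry must vanish (factor i)
  ro <- updateLEvent(v, "removed_occurrence", p)
  expect_equal(probValues(ro)[1], 0)
  expect_equal(probValues(ro)[3], 0.4 * 0.2 * 2 * v@values[2])
  ## sampled ancestor: uniform factor psi (1 - r) = 0.24
  sa <- updateLEvent(v, "sampled_ancestor", p)
  expect_equal(probValues(sa), 0.24 * v@values)
  ## unknown leaf: psi r L(i) + psi (1 - r) L(i + 1)
  ul <- updateLEvent(v, "unknown_leaf", p)
  expect_equal(probValues(ul),
               0.06 * v@values + 0.24 * c(v@values[-1], 0))
  expect_equal(ul@k, 3L)
  ## branching: uniform lambda, one more lineage above
  br <- updateLEvent(v, "branching", p)
  expect_equal(probValues(br), 1.5 * v@values)
  expect_equal(br@k, 1L)
  ## top-boundary convention of the non-removed leaf
  nl <- updateLEvent(v, "nonremoved_leaf", p)
  expect_equal(probValues(nl)[6], 0)
})

test_that("epoch propagation matches the adaptive-ODE oracle", {
  set.seed(11)
  expect_equal(probValues(evolveLEpoch(pv(c(0.4, 0.2, 0.1), 2L), 0,
                                       randomParams())),
               c(0.4, 0.2, 0.1))
  sup <- 0
  for (rep in 1:10) {
    q <- randomParams()
    N <- 40L
    k <- sample(1:4, 1)
    dt <- runif(1, 0.1, 1)
    v0 <- exp(-(0:N) * runif(1, 0.5, 1.2)) * runif(N + 1, 0.5, 1)
    got <- probValues(evolveLEpoch(pv(v0, k), dt, q))
    want <- odeEvolveL(v0, k, dt, q)
    sup <- max(sup, max(abs(got - want)))
  }
  expect_lt(sup, 1e-9)
})

test_that("a single unobserved-fate lineage reproduces p(t, 1 - rho)", {
  ## one lineage, no events below t: L_t(0) = p_t (the empty-product form
  ## of the no-occurrence factorization)
  p <- bdParams(1.2, 0.8, psi = 0.3, omega = 0, rho = 0.6, r = 0.2, tOr = 5)
  L <- initL(1, p@rho, 60)
  for (t in c(0.7, 1.9)) {
    L <- evolveLEpoch(L, t - L@t, p)
    expect_equal(probValues(L)[1], probSingleSample(t, p),
                 tolerance = 1e-10)
    ## and the whole vector is u^i-geometric
    expect_equal(probValues(L),
                 probSingleSample(t, p) * probNoSample(t, p)^(0:60),
                 tolerance = 1e-9)
  }
})

test_that("the no-occurrence closed form matches the numeric sweep", {
  p <- bdParams(1.2, 1, psi = 0.3, omega = 0, rho = 0.5, r = 0.2, tOr = 3)
  ds <- makeDataset(p, seed = 11, gridTimes = c(0.8, 1.7, 2.5))
  Ls <- computeL(ds$sched, p, ds$N, checkTail = FALSE)
  for (j in seq_along(Ls$gridTimes)) {
    ref <- probValues(Ls$vectors[[j]])
    cf <- probValues(closedFormLNoOmega(ds$sched, p, Ls$gridTimes[j], ds$N))
    expect_lt(max(abs(cf - ref)) / max(ref), 1e-6)
  }
  expect_error(closedFormLNoOmega(ds$sched, refParams(1.2), 1, 10), "omega")
})

test_that("the tree-density closed form agrees with both algorithms", {
  for (lambda in c(0.5, 1, 1.5, 2)) {
    p <- bdParams(lambda, 1, psi = 0.3, omega = 0, rho = 0.5, r = 0.2,
                  tOr = 3)
    ds <- makeDataset(p, seed = 40 + round(10 * lambda))
    lc <- fbdTreeDensity(ds$sched, p)
    lb <- logDensityBackward(ds$sched, p, ds$N)
    lf <- logDensityForward(ds$sched, p, ds$N)
    expect_lt(abs(expm1(lb - lc)), 1e-8)
    expect_lt(abs(expm1(lf - lc)), 1e-8)
  }
})

test_that("trivial data and zero-rate events give the expected densities", {
  p <- bdParams(1, 0.5, psi = 0.3, omega = 0.6, rho = 0.5, r = 0.2, tOr = 2)
  tr <- readReconTree("A;")
  sched <- buildSchedule(tr, params = p, gridTimes = numeric())
  expect_equal(logDensityBackward(sched, p, 50),
               log(probSingleSample(2, p)), tolerance = 1e-12)
  ## conditioning on sampling at least one individual
  expect_equal(logDensityBackward(sched, p, 50, conditionOnSampling = TRUE),
               log(probSingleSample(2, p)) - log1p(-probNoSample(2, p)))
  ## a leaf with psi = 0 is impossible data: -Inf, not an exception
  p0 <- bdParams(1, 0.5, psi = 0, omega = 0.6, rho = 0.5, r = 0.2, tOr = 2)
  tr2 <- readReconTree("((A:1,B:0.5[&rm=1]):0.5);")
  sched2 <- buildSchedule(tr2, params = p0, gridTimes = numeric())
  expect_warning(ld <- logDensityBackward(sched2, p0, 30), "zero-density")
  expect_identical(ld, -Inf)
})

test_that("backward density is invariant to where grid points sit", {
  p <- refParams(1.4)
  ds <- makeDataset(p, seed = 7)
  base <- logDensityBackward(ds$sched, p, ds$N)
  withGrid <- buildSchedule(ds$sim@tree, ds$sim@occurrences, p,
                            seq(0, p@tOr, length.out = 13))
  expect_equal(logDensityBackward(withGrid, p, ds$N), base,
               tolerance = 1e-12)
})
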
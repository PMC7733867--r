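test_that("posterior rows are normalized and anchored at k_t", {
  p <- refParams(1.4)
  ds <- makeDataset(p, seed = 7, gridTimes = seq(0, p@tOr, length.out = 9))
  K <- computeK(computeL(ds$sched, p, ds$N), computeM(ds$sched, p, ds$N))
  pm <- posteriorMatrix(K)
  expect_true(all(abs(rowSums(pm) - 1) < 1e-9))
  expect_true(all(pm >= 0))
  ## the support starts at the lineage count: column 1 is n = k_t
  expect_equal(K@k,
               occupop:::kBelowRow(ds$sched)[scheduleEvents(ds$sched)$grid])
  ## at the origin the population is known to be the single origin lineage
  expect_equal(pm[nrow(pm), 1], 1)
  expect_lt(K@logDensityDrift, 1e-8)
})

test_that("complete present-day sampling pins the population at t = 0", {
  p <- bdParams(1, 0.5, psi = 0, omega = 0, rho = 1, r = 0, tOr = 2)
  tr <- readReconTree("((A:1,B:1):1);")
  sched <- buildSchedule(tr, params = p, gridTimes = c(0, 1.5))
  K <- computeK(computeL(sched, p, 40), computeM(sched, p, 40))
  expect_equal(posteriorMatrix(K)[1, 1], 1)   # I_0 = k0 with certainty
})

test_that("the inner product of L and M is constant over the grid", {
  for (seed in c(7, 19, 23)) {
    p <- refParams(1 + 0.3 * (seed %% 3), r = c(0, 0.5, 1)[seed %% 3 + 1])
    ds <- makeDataset(p, seed = seed,
                      gridTimes = seq(0, p@tOr, length.out = 50))
    K <- computeK(computeL(ds$sched, p, ds$N), computeM(ds$sched, p, ds$N))
    expect_lt(K@logDensityDrift, 1e-6)
    expect_equal(logDensity(K), logDensityBackward(ds$sched, p, ds$N),
                 tolerance = 1e-6)
  }
})

test_that("posterior quantiles follow the lower-quantile convention", {
  point <- new("PosteriorGrid", times = 0, k = 3L,
               probs = matrix(c(1, 0, 0, 0), 1), logDensity = 0,
               logDensityDrift = 0)
  q <- posteriorQuantiles(point, c(0.2, 0.5, 0.8))
  expect_equal(unlist(q[, c("q0.2", "q0.5", "q0.8")], use.names = FALSE),
               c(3, 3, 3))
  unif <- new("PosteriorGrid", times = 0, k = 2L,
              probs = matrix(rep(0.25, 4), 1), logDensity = 0,
              logDensityDrift = 0)
  expect_equal(posteriorQuantiles(unif, 0.5)$q0.5, 3)
  expect_equal(posteriorQuantiles(unif, 0.25)$q0.25, 2)
  expect_equal(posteriorQuantiles(unif, 1)$q1, 5)
})

test_that("Doob rates reduce to the unconditioned rates on flat vectors", {
  p <- bdParams(1.3, 0.7, psi = 0.2, omega = 0.1, rho = 0.5, r = 0.3,
                tOr = 2)
  flat <- pv(rep(1, 6), k = 2L)
  rl <- doobRates(flat, p, "L")
  expect_equal(rl$up[-6], p@lambda * (2 * 2 + 0:4))
  expect_equal(rl$down, p@mu * 0:5)
  expect_equal(rl$down[1], 0)
  rm_ <- doobRates(flat, p, "M")
  expect_equal(rm_$down[1], 0)
  expect_equal(rm_$up[-6], p@mu * (1:5))
  expect_equal(rm_$down[-1][-5], p@lambda * (2 * 2 + 1:4 - 1))
})

test_that("the posterior matches exhaustive enumeration on a micro model", {
  ## single rho-tip, mu = psi = omega = 0: with at most two birth events
  ## the joint law of (tree, I_tau) integrates in closed numeric form;
  ## the probability of three or more births bounds the truncation error
  lam <- 0.3; rho <- 0.6; tOr <- 1; tau <- 0.5
  p <- bdParams(lam, 0, psi = 0, omega = 0, rho = rho, r = 0, tOr = tOr)
  ## weights w[i + 1] = P(single-tip tree, I_tau = 1 + i), i = 0, 1, 2
  w <- numeric(3)
  w[1] <- exp(-lam * tOr) * rho                       # no birth at all
  f1 <- function(s)                                   # one birth at s
    lam * exp(-lam * (tOr - s)) * exp(-2 * lam * s) * 2 * rho * (1 - rho)
  w[1] <- w[1] + integrate(f1, 0, tau, rel.tol = 1e-10)$value
  w[2] <- integrate(f1, tau, tOr, rel.tol = 1e-10)$value
  f2 <- function(s1, s2)                              # births at s1 > s2
    lam * exp(-lam * (tOr - s1)) * 2 * lam * exp(-2 * lam * (s1 - s2)) *
      exp(-3 * lam * s2) * 3 * rho * (1 - rho)^2
  dbl <- function(lo1, hi1, lo2fun, hi2fun) {
    integrate(Vectorize(function(s1)
      integrate(function(s2) f2(s1, s2), lo2fun(s1), hi2fun(s1),
                rel.tol = 1e-9)$value), lo1, hi1, rel.tol = 1e-9)$value
  }
  ## both births below tau / one either side / both above tau
  w[1] <- w[1] + dbl(0, tau, function(s1) 0, function(s1) s1)
  w[2] <- w[2] + dbl(tau, tOr, function(s1) 0, function(s1) tau)
  w[3] <- dbl(tau, tOr, function(s1) tau, function(s1) s1)
  enum <- w / sum(w)
  tr <- readReconTree("A;")
  sched <- buildSchedule(tr, params = p, gridTimes = tau)
  K <- computeK(computeL(sched, p, 15), computeM(sched, p, 15))
  got <- posteriorMatrix(K)[1, 1:3]
  ## pure-birth population law is geometric: P(3 or more births)
  pThree <- (1 - exp(-lam * tOr))^3
  expect_lt(tvDist(got / sum(got), enum), max(2e-3, pThree))
  ## the absolute density agrees too
  expect_equal(exp(logDensity(K)), sum(w), tolerance = 5 * pThree)
})
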
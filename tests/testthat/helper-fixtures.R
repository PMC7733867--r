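## Shared fixtures: every dataset is generated in code by the simulator.

## reference through-time sampling regime used across the density checks
refParams <- function(lambda, tOr = 3, omega = 0.6, r = 0.2) {
  bdParams(lambda = lambda, mu = 1, psi = 0.3, omega = omega,
           rho = 0.5, r = r, tOr = tOr)
}

## truncation rule: four times the largest simulated population
recommendedN <- function(sim, minN = 40L) {
  max(minN, 4L * max(sim@trajectory$I))
}

## one simulated dataset with its schedule
makeDataset <- function(params, seed, gridTimes = numeric(),
                        blind = FALSE) {
  sim <- simulateProcess(params, seed = seed, requireTree = TRUE)
  tree <- sim@tree
  occ <- sim@occurrences
  if (blind) {
    tree <- blindRemovalStatus(tree)
    occ <- blindRemovalStatus(occ)
  }
  list(sim = sim, params = params,
       sched = buildSchedule(tree, occ, params, gridTimes),
       N = recommendedN(sim))
}
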
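## Closed-form building blocks of the process.  With E = exp(-Delta t) and
## D(t, z) = (x2 - z) - (x1 - z) E:
##
##   u(t, z) = [x1 (x2 - z) - x2 (x1 - z) E] / D
##   p(t, z) = (1 - z) (Delta/lambda)^2 E / D^2
##
## u solves  du/dt = lambda u^2 - gamma u + mu,  u(0) = z  (the probability
## that a lineage alive at time t leaves no sample at all), and p solves
## dp/dt = (2 lambda u - gamma) p, p(0) = 1 - z (exactly one sample).
## Both are evaluated from these closed forms only; the adaptive-ODE route
## lives in the test oracles.

checkTZ <- function(t, z, params) {
  stopifnot(is(params, "BDParams"))
  if (any(t < 0)) stop("t must be >= 0")
  if (any(z < 0 | z > 1)) stop("z must be in [0, 1]")
}

#' Probability of leaving no sample
#'
#' `probNoSample(t, z, params)` is the probability that a single individual
#' alive at time `t` before present leaves no psi-, omega- or rho-sample at
#' all, when each of its descendants alive at present is independently
#' "missed" with probability `z`.  The shorthand used throughout the model
#' takes `z = 1 - rho`, which is the default.
#'
#' @param t time(s) before present, >= 0 (vectorized).
#' @param z initial value in [0, 1]; defaults to `1 - rho`.
#' @param params a [BDParams-class] object.
#' @return probability value(s) in [0, 1].
#' @seealso [probSingleSample()], [singleSampleRatio()]
#' @export
probNoSample <- function(t, params, z = 1 - params@rho) {
  checkTZ(t, z, params)
  x1 <- params@x1; x2 <- params@x2
  E <- exp(-params@Delta * t)
  (x1 * (x2 - z) - x2 * (x1 - z) * E) / ((x2 - z) - (x1 - z) * E)
}

#' Probability of leaving exactly one sampled individual
#'
#' `probSingleSample(t, z, params)` is the probability that a single
#' individual alive at time `t` before present leads to precisely one
#' sampled individual, under the same `z`-marking as [probNoSample()].
#' `p(0, z) = 1 - z` and `p(t, 1) = 0`.
#'
#' @inheritParams probNoSample
#' @return probability value(s) in [0, 1].
#' @export
probSingleSample <- function(t, params, z = 1 - params@rho) {
  (1 - z) * singleSampleRatio(t, params, z)
}

#' The ratio R(t, z) = p(t, z) / (1 - z)
#'
#' The factor of [probSingleSample()] that is free of the initial
#' condition; `R(0, z) = 1` for every `z`.  It is the building block of the
#' forward generating-function epoch formula.
#'
#' @inheritParams probNoSample
#' @return value(s) >= 0.
#' @export
singleSampleRatio <- function(t, params, z = 1 - params@rho) {
  checkTZ(t, pmin(z, 1), params)
  x1 <- params@x1; x2 <- params@x2
  E <- exp(-params@Delta * t)
  D <- (x2 - z) - (x1 - z) * E
  (params@Delta / params@lambda)^2 * E / D^2
}

#' Epoch log-derivative coefficients a_t and b_t
#'
#' The coefficients entering the closed-form recursion for the forward
#' vector when `omega = 0`: with `E = exp(-Delta t)`,
#' `a_t = (1 - E) / (x2 - x1 E)` and `b_t = (x1 - x2 E) / (x1 x2 (1 - E))`.
#' They are the geometric ratios of the Taylor expansions (around z = 0) of
#' `-log(D(t, z))` and of `log` of the numerator of `u(t, z)`:
#' the z^alpha coefficient of `log R(t, z)` times alpha equals
#' `2 a_t^alpha`, and that of `log u(t, z)` equals
#' `a_t^alpha - b_t^alpha`.  `a_0 = 0`; `b_t` diverges as `t -> 0`
#' (as must any expansion of `log u(0, z) = log z`), and is only ever used
#' with strictly positive time lags.
#'
#' @param t time lag(s), >= 0 (strictly positive where `b` is consumed).
#' @param params a [BDParams-class] object.
#' @return a list with numeric components `a` and `b` (same length as `t`).
#' @export
epochCoeffs <- function(t, params) {
  stopifnot(is(params, "BDParams"), all(t >= 0))
  x1 <- params@x1; x2 <- params@x2
  E <- exp(-params@Delta * t)
  list(a = (1 - E) / (x2 - x1 * E),
       b = (x1 - x2 * E) / (x1 * x2 * (1 - E)))
}
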
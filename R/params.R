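#' Construct birth-death sampling model parameters
#'
#' Builds a [BDParams-class] object from the seven free parameters and
#' computes the derived constants: the total per-capita event rate
#' \eqn{\gamma = \lambda + \mu + \psi + \omega}, the discriminant
#' \eqn{\Delta = \sqrt{\gamma^2 - 4\lambda\mu}} and the two roots
#' \eqn{x_1 \le x_2} of \eqn{\lambda x^2 - \gamma x + \mu}.  The critical
#' case \eqn{\Delta = 0} (equal birth and death rates with no through-time
#' sampling) is rejected: all closed forms used downstream assume
#' \eqn{\Delta > 0}.
#'
#' @param lambda per-capita birth rate, > 0.
#' @param mu per-capita death rate, >= 0.
#' @param psi tree-sampling rate, >= 0.
#' @param omega occurrence-sampling rate, >= 0.
#' @param rho present-day sampling probability in [0, 1].
#' @param r removal probability upon psi-/omega-sampling, in [0, 1].
#' @param tOr origin time (time before present), > 0.
#' @return a validated [BDParams-class] object.
#' @examples
#' p <- bdParams(lambda = 1, mu = 0.5, psi = 0.5, omega = 0,
#'               rho = 0.5, r = 0.2, tOr = 3)
#' discriminantRoots(p)
#' @export
bdParams <- function(lambda, mu, psi = 0, omega = 0, rho = 1, r = 0, tOr) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0)
    stop("lambda must be a single positive number")
  gamma <- lambda + mu + psi + omega
  disc <- gamma^2 - 4 * lambda * mu
  Delta <- sqrt(max(disc, 0))
  new("BDParams",
      lambda = lambda, mu = mu, psi = psi, omega = omega,
      rho = rho, r = r, tOr = tOr,
      gamma = gamma, Delta = Delta,
      x1 = (gamma - Delta) / (2 * lambda),
      x2 = (gamma + Delta) / (2 * lambda))
}

#' Discriminant and roots of the birth-death quadratic
#'
#' Returns \eqn{\Delta} and the roots \eqn{x_1 \le x_2} of
#' \eqn{\lambda x^2 - \gamma x + \mu}.  These satisfy
#' \eqn{x_1 x_2 = \mu/\lambda}, \eqn{x_1 + x_2 = \gamma/\lambda}, and
#' \eqn{\Delta \ge |\lambda - \mu|} with equality exactly when
#' \eqn{\psi = \omega = 0}.
#'
#' @param params a [BDParams-class] object.
#' @return named numeric vector `c(Delta, x1, x2)`.
#' @export
discriminantRoots <- function(params) {
  stopifnot(is(params, "BDParams"))
  c(Delta = params@Delta, x1 = params@x1, x2 = params@x2)
}
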
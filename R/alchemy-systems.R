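## One-dimensional toy alchemical systems.  They stand in for the solvated
## protein (buried site) and the Ala-Met-Ala tripeptide (exposed site)
## endpoints: cheap enough to sample exhaustively, with reference delta-G
## values from closed forms or deterministic Boltzmann quadrature.

#' Harmonic toy alchemical system
#'
#' A particle in a harmonic well whose stiffness interpolates linearly
#' from `k0` to `k1` with lambda.  The endpoint free-energy difference has
#' the closed form \eqn{\Delta G = (k_B T / 2) \ln(k_1 / k_0)}
#' (0.4132 kcal/mol for 1 -> 4 kcal/mol/A^2 at 300 K).
#'
#' @param k0,k1 endpoint stiffness, kcal/mol/A^2.
#' @param temperature K.
#' @param stepSize Metropolis proposal SD, A.
#' @return a [ToyAlchemicalSystem-class].
#' @export
harmonicAlchemicalSystem <- function(k0 = 1, k1 = 4, temperature = 300,
                                     stepSize = 1) {
  stopifnot(k0 > 0, k1 > 0)
  new("ToyAlchemicalSystem",
      energy = function(x, lambda)
        0.5 * ((1 - lambda) * k0 + lambda * k1) * x^2,
      stepSize = stepSize, temperature = temperature,
      closedFormDg = 0.5 * kT(temperature) * log(k1 / k0),
      label = sprintf("harmonic k %g -> %g", k0, k1))
}

## Deterministic Boltzmann quadrature of -kT ln(Z1/Z0) for a 1-D system.
quadratureDg <- function(energy, temperature, lower, upper, n = 20001L) {
  x <- seq(lower, upper, length.out = n)
  beta <- 1 / kT(temperature)
  z <- function(lam) {
    u <- energy(x, lam)
    m <- min(u)
    ## trapezoid in x of exp(-beta u), stabilized
    w <- exp(-beta * (u - m))
    log(sum((w[-1] + w[-n]) / 2) * (x[2] - x[1])) - beta * m
  }
  -kT(temperature) * (z(1) - z(0))
}

#' Alchemical site system: soft-core insertion next to fixed neighbors
#'
#' A restrained particle on a line, with a lambda-coupled soft-core
#' Lennard-Jones interaction to fixed neighbor particles.  With close
#' neighbors (a buried site, tight packing around the sulphur) switching
#' the interaction on is costly and \eqn{\Delta G > 0}; with distant
#' neighbors (an exposed, tripeptide-like site) the transformation is
#' nearly free.  The endpoint \eqn{\Delta G} is computed by deterministic
#' Boltzmann quadrature and stored as the reference value.
#'
#' @param neighborDistances positions of the fixed neighbors, A.
#' @param epsilon,rmin,alpha soft-core Lennard-Jones parameters (see
#'   [softcorePotential()]).
#' @param restraintK harmonic restraint stiffness, kcal/mol/A^2.
#' @param temperature K.
#' @param stepSize Metropolis proposal SD, A.
#' @param label description.
#' @return a [ToyAlchemicalSystem-class].
#' @export
siteAlchemicalSystem <- function(neighborDistances, epsilon = 0.3,
                                 rmin = 4, alpha = 0.5, restraintK = 1,
                                 temperature = 300, stepSize = 0.8,
                                 label = "site") {
  stopifnot(length(neighborDistances) >= 1)
  energy <- function(x, lambda) {
    u <- 0.5 * restraintK * x^2
    for (d in neighborDistances)
      u <- u + softcorePotential(abs(x - d), lambda, epsilon, rmin, alpha)
    u
  }
  span <- max(abs(neighborDistances)) + 10
  ref <- quadratureDg(energy, temperature, -span, span)
  new("ToyAlchemicalSystem", energy = energy, stepSize = stepSize,
      temperature = temperature, closedFormDg = ref, label = label)
}

#' Identity toy system
#'
#' The same harmonic well at both endpoints: every energy-difference
#' sample is exactly zero and every estimator must return delta-G = 0.
#' Used as the cycle-closure control.
#'
#' @param k stiffness, kcal/mol/A^2.
#' @param temperature K.
#' @return a [ToyAlchemicalSystem-class].
#' @export
identityAlchemicalSystem <- function(k = 1, temperature = 300) {
  new("ToyAlchemicalSystem",
      energy = function(x, lambda) 0.5 * k * x^2,
      stepSize = 1, temperature = temperature, closedFormDg = 0,
      label = "identity")
}
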
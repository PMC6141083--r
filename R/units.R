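## Physical constants used throughout.  Energies are kcal/mol, lengths
## Angstrom, times ps unless a function documents otherwise.

#' Physical constants
#'
#' Constants fixed by convention across the package: the Boltzmann constant
#' in kcal/mol/K, the Coulomb constant in kcal A / (mol e^2), and the
#' conversion from kcal/mol/A to piconewton.
#'
#' @format Named numeric values.
#' @name constants
NULL

#' @rdname constants
#' @export
kBoltzmann <- 0.0019872041

#' @rdname constants
#' @export
coulombConstant <- 332.0636

#' @rdname constants
#' @export
pnPerKcalMolA <- 69.4786

#' Thermal energy at a temperature
#'
#' @param temperature Kelvin.
#' @return kT in kcal/mol (0.59616 kcal/mol at 300 K).
#' @export
kT <- function(temperature = 300) kBoltzmann * temperature

#' Convert a force between kcal/mol/A and pN
#'
#' @param force numeric force value(s).
#' @param from unit of `force`, `"kcalmolA"` or `"pN"`.
#' @return force in the other unit.
#' @export
convertForce <- function(force, from = c("kcalmolA", "pN")) {
  from <- match.arg(from)
  if (from == "kcalmolA") force * pnPerKcalMolA else force / pnPerKcalMolA
}

## Internal condition helpers: every contract violation raises a classed
## condition so callers (and tests) can discriminate failure modes.
oxStop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "oxfold_error")))
}

## Run code with the global RNG stream saved and restored, seeded locally.
withLocalSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## log(mean(exp(x))) guarded against overflow.
logMeanExp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}
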
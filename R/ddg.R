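## Thermodynamic-cycle combination of the two alchemical legs.

#' Thermodynamic-cycle delta-delta-G of folding
#'
#' Instead of folding the protein in both oxidation states, the cycle
#' closes through the two alchemical legs:
#' \deqn{\Delta\Delta G = \Delta G_{fold,ox} - \Delta G_{fold,wt}
#'       = \Delta G_{alch,folded} - \Delta G_{alch,unfolded}.}
#' A positive value means the oxidation is thermodynamically unfavorable
#' for folding.  Standard errors combine in quadrature.
#'
#' @param folded [FreeEnergyEstimate-class] for the folded-state leg.
#' @param unfolded [FreeEnergyEstimate-class] for the unfolded-state leg
#'   (e.g. the Ala-Met-Ala tripeptide proxy).
#' @return a [DDGResult-class].
#' @export
ddgCycle <- function(folded, unfolded) {
  stopifnot(is(folded, "FreeEnergyEstimate"),
            is(unfolded, "FreeEnergyEstimate"))
  if (abs(folded@temperature - unfolded@temperature) > 1e-9)
    oxStop("folded and unfolded legs were estimated at different temperatures",
           "oxfold_domain_error")
  new("DDGResult", folded = folded, unfolded = unfolded,
      ddg = folded@deltaG - unfolded@deltaG,
      standardError = sqrt(folded@standardError^2 +
                           unfolded@standardError^2))
}

#' Construct a FreeEnergyEstimate directly
#'
#' For combining externally obtained legs (e.g. replicate means) into a
#' cycle.
#'
#' @param deltaG kcal/mol.
#' @param standardError kcal/mol.
#' @param method estimator label.
#' @param nWindows transitions combined.
#' @param temperature K.
#' @return a [FreeEnergyEstimate-class].
#' @export
freeEnergyEstimate <- function(deltaG, standardError, method = "BAR",
                               nWindows = 1L, temperature = 300) {
  new("FreeEnergyEstimate", deltaG = deltaG, standardError = standardError,
      method = method, nWindows = as.integer(nWindows),
      temperature = temperature)
}
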
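## Switched nonbonded interaction energies between two atom groups.

#' CHARMM-style switching function
#'
#' \eqn{S(r) = 1} for \eqn{r \le r_{on}}, 0 for \eqn{r \ge r_{off}}, and
#' \deqn{S(r) = \frac{(r_{off}^2 - r^2)^2 (r_{off}^2 + 2 r^2 - 3 r_{on}^2)}
#'   {(r_{off}^2 - r_{on}^2)^3}}
#' between, which is C^1-continuous at both ends.  Conventional cutoffs
#' for this system: switch on at 8 A, off at 10 A.
#'
#' @param r distance(s), A.
#' @param switchOn A.
#' @param cutoff A.
#' @return switching factor(s) in [0, 1].
#' @export
switchingFunction <- function(r, switchOn = 8, cutoff = 10) {
  s <- ifelse(r <= switchOn, 1,
       ifelse(r >= cutoff, 0,
              (cutoff^2 - r^2)^2 * (cutoff^2 + 2 * r^2 - 3 * switchOn^2) /
                (cutoff^2 - switchOn^2)^3))
  s
}

#' Switched Coulomb + Lennard-Jones energy between two groups
#'
#' Pairwise sum over a-b pairs of the Coulomb term
#' \eqn{k_e q_i q_j / r} (\eqn{k_e} = 332.0636 kcal A / mol e^2) and the
#' Lennard-Jones term \eqn{\epsilon_{ij}[(r_{min,ij}/r)^{12} -
#' 2 (r_{min,ij}/r)^6]} with geometric-mean well depths and
#' arithmetic-mean minimum distances, each multiplied by
#' [switchingFunction()].  Pairs beyond the cutoff contribute nothing.
#'
#' @param structure a parameterized [Structure-class].
#' @param groupA,groupB disjoint [AtomSet-class] objects.
#' @param cutoff A (default 10).
#' @param switchOn A (default 8).
#' @return an [EnergyPair-class].
#' @export
interactionEnergy <- function(structure, groupA, groupB, cutoff = 10,
                              switchOn = 8) {
  stopifnot(is(structure, "Structure"))
  if (length(intersect(groupA@indices, groupB@indices)))
    oxStop("groups must be disjoint", "oxfold_selection_error")
  a <- structure@atoms
  need <- c("charge", "ljEpsilon", "ljRminHalf")
  if (anyNA(a[c(groupA@indices, groupB@indices), need]))
    oxStop("atoms lack nonbonded parameters; run assignParams() first",
           "oxfold_parameterization_error")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  ia <- groupA@indices; ib <- groupB@indices
  pa <- xyz[ia, , drop = FALSE]; pb <- xyz[ib, , drop = FALSE]
  d2 <- outer(rowSums(pa^2), rep(1, length(ib))) +
    outer(rep(1, length(ia)), rowSums(pb^2)) - 2 * (pa %*% t(pb))
  d2[d2 < 0] <- 0
  r <- sqrt(d2)
  if (any(r < 1e-9))
    oxStop("zero interatomic distance between the groups",
           "oxfold_geometry_error")
  mask <- r < cutoff
  if (!any(mask))
    return(new("EnergyPair", electrostatic = 0, vanDerWaals = 0,
               cutoff = cutoff, switchOn = switchOn))
  S <- switchingFunction(r, switchOn, cutoff)
  qq <- outer(a$charge[ia], a$charge[ib])
  elec <- sum((coulombConstant * qq / r * S)[mask])
  eps <- sqrt(outer(a$ljEpsilon[ia], a$ljEpsilon[ib]))
  rmin <- outer(a$ljRminHalf[ia], a$ljRminHalf[ib], "+")
  sr6 <- (rmin / r)^6
  lj <- sum((eps * (sr6^2 - 2 * sr6) * S)[mask])
  new("EnergyPair", electrostatic = elec, vanDerWaals = lj,
      cutoff = cutoff, switchOn = switchOn)
}
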
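## Geometric hydrogen-bond detection.
##
## Criteria follow the hydration analysis convention for sulfoxide
## residues: H...acceptor distance <= 2.7 A and donor-H...acceptor angle
## >= 120 degrees, both boundaries inclusive.  Hydrogens are attached to
## their donor heavy atom geometrically (name starts with H, distance
## < 1.2 A) because plain PDB fixtures carry no bond table.

#' Hydrogen-bond criteria constructor
#'
#' @param maxHAcceptorDistance A (default 2.7).
#' @param minDonorAngle degrees (default 120).
#' @return an [HBondCriteria-class].
#' @export
hbondCriteria <- function(maxHAcceptorDistance = 2.7, minDonorAngle = 120) {
  new("HBondCriteria", maxHAcceptorDistance = maxHAcceptorDistance,
      minDonorAngle = minDonorAngle)
}

## Hydrogens covalently attached to a donor heavy atom, by the documented
## geometric rule.
attachedHydrogens <- function(a, xyz, donor) {
  isH <- toupper(substr(a$name, 1, 1)) == "H" | toupper(a$element) == "H"
  cand <- setdiff(which(isH), donor)
  if (!length(cand)) return(integer(0))
  d <- sqrt(rowSums(sweep(xyz[cand, , drop = FALSE], 2, xyz[donor, ])^2))
  cand[d < 1.2]
}

#' Detect hydrogen bonds in one conformation
#'
#' Enumerates (donor heavy atom, donor hydrogen, acceptor) triples where
#' the hydrogen sits within the distance cutoff of the acceptor and the
#' donor-H...acceptor angle meets the angular cutoff.  Donor heavy atoms
#' without any attached hydrogen are skipped with a warning (they cannot
#' donate), not an error.
#'
#' @param structure a [Structure-class].
#' @param donors [AtomSet-class] of donor heavy atoms.
#' @param acceptors [AtomSet-class] of acceptor atoms.
#' @param criteria an [HBondCriteria-class].
#' @return data.frame with columns donor, hydrogen, acceptor (atom
#'   indices), distance (A), angle (degrees); zero rows when no bond
#'   qualifies.
#' @export
detectHBondsFrame <- function(structure, donors, acceptors,
                              criteria = hbondCriteria()) {
  stopifnot(is(structure, "Structure"))
  a <- structure@atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  isH <- toupper(substr(a$name, 1, 1)) == "H" | toupper(a$element) == "H"
  out <- list()
  for (d in donors@indices) {
    if (isH[d]) next   # hydrogens are not donor heavy atoms
    hs <- attachedHydrogens(a, xyz, d)
    if (!length(hs)) {
      warning(sprintf("donor atom %s %d/%s has no attached hydrogen; skipped",
                      a$resname[d], a$resid[d], a$name[d]), call. = FALSE)
      next
    }
    for (h in hs) {
      acc <- setdiff(acceptors@indices, c(d, h))
      if (!length(acc)) next
      dv <- sweep(xyz[acc, , drop = FALSE], 2, xyz[h, ])
      dist <- sqrt(rowSums(dv^2))
      hd <- xyz[d, ] - xyz[h, ]
      nhd <- sqrt(sum(hd^2))
      cosang <- (dv %*% hd) / (dist * nhd)
      ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      ok <- dist <= criteria@maxHAcceptorDistance + 1e-9 &
        ang >= criteria@minDonorAngle - 1e-9
      if (any(ok))
        out[[length(out) + 1L]] <- data.frame(
          donor = d, hydrogen = h, acceptor = acc[ok],
          distance = dist[ok], angle = ang[ok])
    }
  }
  if (!length(out))
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), distance = numeric(0),
                      angle = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fraction of frames with at least one hydrogen bond between two groups
#'
#' The hydration measure for a sulfoxide residue: the fraction of
#' trajectory frames in which the residue group and the solvent group
#' share at least one qualifying hydrogen bond, in either donor/acceptor
#' role.
#'
#' @param trajectory a [Trajectory-class].
#' @param residueGroup,solventGroup [AtomSet-class] objects.
#' @param criteria an [HBondCriteria-class].
#' @return fraction in [0, 1].
#' @export
hbondFraction <- function(trajectory, residueGroup, solventGroup,
                          criteria = hbondCriteria()) {
  stopifnot(is(trajectory, "Trajectory"))
  if (length(trajectory@frames) == 0)
    oxStop("empty trajectory", "oxfold_domain_error")
  hit <- vapply(trajectory@frames, function(f) {
    b1 <- suppressWarnings(
      detectHBondsFrame(f, residueGroup, solventGroup, criteria))
    if (nrow(b1) > 0) return(TRUE)
    b2 <- suppressWarnings(
      detectHBondsFrame(f, solventGroup, residueGroup, criteria))
    nrow(b2) > 0
  }, logical(1))
  mean(hit)
}
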
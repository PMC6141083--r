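## Shrake-Rupley solvent accessible surface area with a deterministic
## golden-section spiral point set.

#' Deterministic quasi-uniform points on the unit sphere
#'
#' Golden-section spiral lattice used by the Shrake-Rupley quadrature; the
#' point set depends only on `n`, making SASA values reproducible.
#'
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
spherePoints <- function(n) {
  k <- seq_len(n)
  z <- 1 - (2 * k - 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- k * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent accessible surface area of one conformation
#'
#' Shrake-Rupley sphere sampling: each atom's van der Waals sphere is
#' expanded by the probe radius and covered with `nPoints` spiral points; a
#' point counts as accessible when it lies inside no other expanded
#' sphere.  All atoms of the structure occlude, whether or not they belong
#' to `group`.
#'
#' @param structure a [Structure-class] whose atoms all carry radii.
#' @param group [AtomSet-class] of atoms to report (default: all atoms).
#' @param probe probe radius, A (default 1.4, a water-sized probe).
#' @param nPoints quadrature points per atom (>= 32; default 960).
#' @return a [SASAResult-class].
#' @export
sasaFrame <- function(structure, group = NULL, probe = 1.4, nPoints = 960L) {
  stopifnot(is(structure, "Structure"))
  if (nPoints < 32) oxStop("nPoints must be >= 32", "oxfold_domain_error")
  a <- structure@atoms
  if (anyNA(a$radius))
    oxStop("all atoms need radii; run assignParams() first",
           "oxfold_parameterization_error")
  idx <- if (is.null(group)) seq_len(nrow(a)) else group@indices
  xyz <- as.matrix(a[, c("x", "y", "z")])
  R <- a$radius + probe
  pts <- spherePoints(nPoints)
  per <- numeric(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    Ri <- R[i]
    d2 <- colSums((t(xyz) - xyz[i, ])^2)
    nb <- which(d2 < (Ri + R)^2)
    nb <- nb[nb != i]
    if (!length(nb)) {
      per[k] <- 4 * pi * Ri^2
      next
    }
    p <- sweep(pts * Ri, 2, xyz[i, ], "+")
    cn <- xyz[nb, , drop = FALSE]
    dd <- outer(rowSums(p^2), rep(1, length(nb))) +
      outer(rep(1, nPoints), rowSums(cn^2)) - 2 * (p %*% t(cn))
    inside <- sweep(dd, 2, R[nb]^2, "<")
    acc <- rowSums(inside) == 0
    per[k] <- 4 * pi * Ri^2 * mean(acc)
  }
  names(per) <- as.character(idx)
  new("SASAResult", perAtom = per, groupTotal = sum(per),
      probeRadius = probe, nPoints = as.integer(nPoints))
}

#' SASA time series over a trajectory
#'
#' One group total per frame; times come from the trajectory's frame
#' interval (first frame at t = 0).
#'
#' @inheritParams sasaFrame
#' @param trajectory a [Trajectory-class].
#' @return a [Series-class] labelled `"sasa_A2"`.
#' @export
sasaSeries <- function(trajectory, group = NULL, probe = 1.4,
                       nPoints = 960L) {
  stopifnot(is(trajectory, "Trajectory"))
  vals <- vapply(trajectory@frames, function(f)
    sasaFrame(f, group, probe, nPoints)@groupTotal, numeric(1))
  new("Series",
      times = (seq_along(vals) - 1) * trajectory@frameInterval,
      values = vals, label = "sasa_A2")
}
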
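## Soft-core van der Waals coupling.

#' Beutler-style soft-core Lennard-Jones potential
#'
#' \deqn{V(r, \lambda) = \lambda \, 4\epsilon \left[
#'   \frac{1}{(\alpha(1-\lambda) + (r/\sigma)^6)^2} -
#'   \frac{1}{\alpha(1-\lambda) + (r/\sigma)^6} \right]}
#' with \eqn{\sigma = r_{min} / 2^{1/6}}.  The \eqn{\alpha(1-\lambda)}
#' pad keeps the potential finite at r = 0 for every \eqn{\lambda < 1},
#' removing the singularity that plain lambda-scaling would hit when an
#' atom is being created or deleted; at \eqn{\lambda = 1} it reduces to
#' the standard Lennard-Jones potential and at \eqn{\lambda = 0} it
#' vanishes identically.
#'
#' @param r distance(s), A (r >= 0).
#' @param lambda coupling in [0, 1].
#' @param epsilon well depth, kcal/mol.
#' @param rmin position of the (fully coupled) minimum, A.
#' @param alpha soft-core parameter (> 0, default 0.5).
#' @return energy, kcal/mol; finite for all inputs (totality is the point).
#' @export
softcorePotential <- function(r, lambda, epsilon, rmin, alpha = 0.5) {
  stopifnot(all(r >= 0), lambda >= 0, lambda <= 1, alpha > 0)
  if (lambda == 0) return(rep(0, length(r)))
  sigma <- rmin / 2^(1 / 6)
  denom <- alpha * (1 - lambda) + (r / sigma)^6
  v <- lambda * 4 * epsilon * (1 / denom^2 - 1 / denom)
  ## only at lambda = 1 and r = 0 can the pad vanish: the plain LJ wall
  v[denom == 0] <- Inf
  v
}
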
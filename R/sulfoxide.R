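## Methionine -> methionine sulfoxide model building.
##
## One oxygen (OD) is bonded to the sulphur: placed along the negative
## bisector of the CG-SD-CE angle at a fixed S=O bond length, then rotated
## about the CG-SD axis over a coarse angular grid to relieve steric
## clashes against the (fixed) environment.  This geometric clash relief
## replaces force-field minimization; all atoms other than the mutated
## residue stay exactly where they were.

rodrigues <- function(v, axis, theta) {
  a <- axis / sqrt(sum(axis^2))
  v * cos(theta) + crossProd3(a, v) * sin(theta) +
    a * sum(a * v) * (1 - cos(theta))
}

crossProd3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## Steric-overlap score of a candidate oxygen position: squared overlap
## depth against every atom outside the mutated residue.
sulfoxideOverlap <- function(pos, envXYZ, clashDistance) {
  if (nrow(envXYZ) == 0) return(0)
  d <- sqrt(rowSums(sweep(envXYZ, 2, pos)^2))
  sum(pmax(0, clashDistance - d)^2)
}

#' Convert a methionine residue to methionine sulfoxide
#'
#' Oxidizing agents add exactly one oxygen to the methionine sulphur, so
#' the builder adds a single OD atom bonded to SD and renames the residue
#' (default `"MSX"`).  The oxygen starts on the negative bisector of the
#' CG-SD-CE angle at `bondLength` and is rotated about the CG-SD axis over
#' `gridAngles` evenly spaced angles; the angle with the lowest
#' steric-overlap score against all atoms outside the residue wins (ties
#' go to the smallest angle).  Every other atom keeps its coordinates.
#'
#' @param structure a [Structure-class].
#' @param residueId residue id of the methionine to oxidize.
#' @param chain chain id (only needed when the residue id is ambiguous).
#' @param bondLength S=O bond length, A (default 1.50).
#' @param gridAngles number of candidate rotation angles (default 24,
#'   i.e. 15 degree steps).
#' @param clashDistance overlap threshold against environment atoms, A.
#' @param sulfoxideName residue name given to the oxidized residue.
#' @param details if TRUE, return a list with the structure plus the
#'   chosen angle and the per-angle overlap scores.
#' @return the modified [Structure-class] (or a list when
#'   `details = TRUE`): one atom more, one residue renamed.
#' @export
buildSulfoxide <- function(structure, residueId, chain = NULL,
                           bondLength = 1.50, gridAngles = 24L,
                           clashDistance = 2.8, sulfoxideName = "MSX",
                           details = FALSE) {
  stopifnot(is(structure, "Structure"))
  a <- structure@atoms
  inRes <- a$resid == residueId
  if (!is.null(chain)) inRes <- inRes & a$chain == chain
  if (!any(inRes))
    oxStop(paste("no residue with id", residueId), "oxfold_empty_selection")
  resn <- unique(a$resname[inRes])
  if (!identical(resn, "MET"))
    oxStop(paste0("residue ", residueId, " is ", paste(resn, collapse = "/"),
                  ", not MET"), "oxfold_type_error")
  need <- c("CG", "SD", "CE")
  have <- a$name[inRes]
  if (!all(need %in% have))
    oxStop(paste("incomplete methionine side chain; missing:",
                 paste(setdiff(need, have), collapse = ", ")),
           "oxfold_incomplete_residue")
  pick <- function(nm) unlist(a[inRes & a$name == nm, c("x", "y", "z")])
  cg <- pick("CG"); sdp <- pick("SD"); ce <- pick("CE")
  u1 <- (cg - sdp) / sqrt(sum((cg - sdp)^2))
  u2 <- (ce - sdp) / sqrt(sum((ce - sdp)^2))
  bis <- u1 + u2
  bis <- bis / sqrt(sum(bis^2))
  base <- -bis * bondLength          # negative bisector, from SD
  axis <- -u1                        # CG -> SD direction
  envXYZ <- as.matrix(a[!inRes, c("x", "y", "z")])
  angles <- seq(0, 2 * pi, length.out = gridAngles + 1L)[seq_len(gridAngles)]
  scores <- vapply(angles, function(th)
    sulfoxideOverlap(sdp + rodrigues(base, axis, th), envXYZ, clashDistance),
    numeric(1))
  best <- which.min(scores)          # which.min takes the earliest tie
  od <- sdp + rodrigues(base, axis, angles[best])

  ## insert OD after the last atom of the residue to keep it contiguous
  lastIdx <- max(which(inRes))
  newRow <- a[lastIdx, ]
  newRow$serial <- max(a$serial) + 1L
  newRow$name <- "OD"
  newRow$element <- "O"
  newRow$x <- od[1]; newRow$y <- od[2]; newRow$z <- od[3]
  newRow$radius <- NA_real_; newRow$charge <- NA_real_
  newRow$ljEpsilon <- NA_real_; newRow$ljRminHalf <- NA_real_
  a <- rbind(a[seq_len(lastIdx), ], newRow,
             if (lastIdx < nrow(a)) a[(lastIdx + 1):nrow(a), ])
  rownames(a) <- NULL
  a$resname[a$resid == residueId &
            (if (is.null(chain)) TRUE else a$chain == chain)] <- sulfoxideName
  out <- structure
  out@atoms <- a
  validObject(out)
  if (details)
    list(structure = out, angle = angles[best] * 180 / pi,
         score = scores[best], scores = scores)
  else out
}
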
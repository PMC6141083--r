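## Generics and accessors.  Slot access from user code should go through
## these rather than `@`.

#' Atom table of a structure
#' @param x a [Structure-class].
#' @return data.frame of atoms.
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname atoms
#' @export
setMethod("atoms", "Structure", function(x) x@atoms)

#' Number of atoms
#' @param x a [Structure-class] or [Trajectory-class].
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "Structure", function(x) nrow(x@atoms))

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "Trajectory", function(x) nrow(x@frames[[1]]@atoms))

#' Coordinates of a structure
#' @param x a [Structure-class].
#' @return n x 3 numeric matrix (A).
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname coords
#' @export
setMethod("coords", "Structure", function(x)
  as.matrix(x@atoms[, c("x", "y", "z")]))

#' Frames of a trajectory
#' @param x a [Trajectory-class].
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname frames
#' @export
setMethod("frames", "Trajectory", function(x) x@frames)

#' Number of frames
#' @param x a [Trajectory-class].
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname nFrames
#' @export
setMethod("nFrames", "Trajectory", function(x) length(x@frames))

#' Frame interval of a trajectory (ps)
#' @param x a [Trajectory-class].
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' @rdname frameInterval
#' @export
setMethod("frameInterval", "Trajectory", function(x) x@frameInterval)

#' Atom indices of a selection
#' @param x an [AtomSet-class].
#' @export
setGeneric("indices", function(x) standardGeneric("indices"))

#' @rdname indices
#' @export
setMethod("indices", "AtomSet", function(x) x@indices)

#' Times and values of a series
#' @param x a [Series-class] or [PullingTrace-class].
#' @export
setGeneric("seriesTimes", function(x) standardGeneric("seriesTimes"))

#' @rdname seriesTimes
#' @export
setMethod("seriesTimes", "Series", function(x) x@times)

#' @rdname seriesTimes
#' @export
setGeneric("seriesValues", function(x) standardGeneric("seriesValues"))

#' @rdname seriesTimes
#' @export
setMethod("seriesValues", "Series", function(x) x@values)

#' Estimated free-energy difference (kcal/mol)
#' @param x a [FreeEnergyEstimate-class] or [DDGResult-class].
#' @export
setGeneric("deltaG", function(x) standardGeneric("deltaG"))

#' @rdname deltaG
#' @export
setMethod("deltaG", "FreeEnergyEstimate", function(x) x@deltaG)

#' @rdname deltaG
#' @export
setMethod("deltaG", "DDGResult", function(x) x@ddg)

#' Standard error of an estimate (kcal/mol)
#' @param x a [FreeEnergyEstimate-class] or [DDGResult-class].
#' @export
setGeneric("standardError", function(x) standardGeneric("standardError"))

#' @rdname standardError
#' @export
setMethod("standardError", "FreeEnergyEstimate", function(x) x@standardError)

#' @rdname standardError
#' @export
setMethod("standardError", "DDGResult", function(x) x@standardError)

#' Trace data of a pulling run
#' @param x a [PullingTrace-class].
#' @return data.frame of recorded quantities.
#' @export
setGeneric("traceData", function(x) standardGeneric("traceData"))

#' @rdname traceData
#' @export
setMethod("traceData", "PullingTrace", function(x) x@data)

#' Did rupture detection find an event?
#' @param x a [RuptureEvent-class].
#' @export
setGeneric("hasEvent", function(x) standardGeneric("hasEvent"))

#' @rdname hasEvent
#' @export
setMethod("hasEvent", "RuptureEvent", function(x) x@event)

#' Peak force of a rupture event
#' @param x a [RuptureEvent-class].
#' @param unit `"pN"` or `"kcalmolA"`.
#' @export
setGeneric("peakForce", function(x, unit = "pN") standardGeneric("peakForce"))

#' @rdname peakForce
#' @export
setMethod("peakForce", "RuptureEvent", function(x, unit = "pN") {
  unit <- match.arg(unit, c("pN", "kcalmolA"))
  if (!x@event) return(NA_real_)
  if (unit == "pN") x@peakForcePN else x@peakForce
})

## ---- show methods -------------------------------------------------------

setMethod("show", "Structure", function(object) {
  a <- object@atoms
  cat(sprintf("Structure: %d atoms, %d residues, chains %s [model %d]\n",
              nrow(a), length(unique(paste(a$chain, a$resid))),
              paste(unique(a$chain), collapse = ","), object@modelId))
  if (nzchar(object@provenance))
    cat("  provenance:", object@provenance, "\n")
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d frames x %d atoms, %.6g ps/frame\n",
              length(object@frames), nrow(object@frames[[1]]@atoms),
              object@frameInterval))
})

setMethod("show", "AtomSet", function(object) {
  cat(sprintf("AtomSet '%s': %d of %d atoms\n", object@label,
              length(object@indices), object@universeSize))
})

setMethod("show", "Series", function(object) {
  cat(sprintf("Series '%s': %d samples, t = %.6g..%.6g ps\n", object@label,
              length(object@times), object@times[1],
              object@times[length(object@times)]))
})

setMethod("show", "SASAResult", function(object) {
  cat(sprintf("SASA: %.2f A^2 over %d atoms (probe %.2f A, %d points)\n",
              object@groupTotal, length(object@perAtom),
              object@probeRadius, object@nPoints))
})

setMethod("show", "EnergyPair", function(object) {
  cat(sprintf(
    "Interaction energy: elec %.4f, vdW %.4f kcal/mol (switch %g-%g A)\n",
    object@electrostatic, object@vanDerWaals, object@switchOn,
    object@cutoff))
})

setMethod("show", "LambdaSchedule", function(object) {
  cat(sprintf(
    "LambdaSchedule: %d states, %.4g ps/state (%.0f%% equilibration), total %.4g ns\n",
    object@nWindows, object@windowLength,
    100 * object@equilibrationFraction,
    object@nWindows * object@windowLength / 1000))
})

setMethod("show", "WorkData", function(object) {
  nf <- sum(vapply(object@forward, length, integer(1)))
  nb <- sum(vapply(object@backward, length, integer(1)))
  cat(sprintf(
    "WorkData: %d transitions, %d forward / %d backward samples, T = %g K\n",
    length(object@lambdas) - 1, nf, nb, object@temperature))
})

setMethod("show", "FreeEnergyEstimate", function(object) {
  cat(sprintf("deltaG [%s] = %.4f +/- %.4f kcal/mol (%d windows, %g K)\n",
              object@method, object@deltaG, object@standardError,
              object@nWindows, object@temperature))
})

setMethod("show", "DDGResult", function(object) {
  cat(sprintf("ddG(folding) = %.4f +/- %.4f kcal/mol\n", object@ddg,
              object@standardError))
  cat(sprintf("  folded:   %.4f +/- %.4f\n", object@folded@deltaG,
              object@folded@standardError))
  cat(sprintf("  unfolded: %.4f +/- %.4f\n", object@unfolded@deltaG,
              object@unfolded@standardError))
})

setMethod("show", "ToyModel", function(object) {
  cat(sprintf(
    "ToyModel: %d beads (%d body, %d helix), %d bonds, %d contacts (%d oxidizable), oxidation factor %g\n",
    nrow(object@positions), sum(object@types == "body"),
    sum(object@types == "helix"), nrow(object@bonds),
    nrow(object@contacts), sum(object@contacts$oxidizable),
    object@oxidationFactor))
})

setMethod("show", "PullingTrace", function(object) {
  d <- object@data
  cat(sprintf(
    "PullingTrace: %d records over %.4g ns, max force %.1f pN\n",
    nrow(d), max(d$time_ps) / 1000, max(d$force_pN)))
})

setMethod("show", "RuptureEvent", function(object) {
  if (!object@event) {
    cat("RuptureEvent: no event (SASA never exceeded threshold)\n")
  } else {
    cat(sprintf(
      "RuptureEvent: crossing %.6g ps, peak %.1f pN at %.6g ps (threshold %g A^2, window %g ps)\n",
      object@crossingTime, object@peakForcePN, object@peakTime,
      object@threshold, object@window))
  }
})

setMethod("show", "ToyAlchemicalSystem", function(object) {
  cat(sprintf("ToyAlchemicalSystem '%s' (T = %g K", object@label,
              object@temperature))
  if (is.finite(object@closedFormDg))
    cat(sprintf(", reference dG = %.4f kcal/mol", object@closedFormDg))
  cat(")\n")
})
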
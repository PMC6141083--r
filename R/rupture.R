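## Rupture-force identification: anchor the force peak to the moment the
## hydrophobic core becomes solvent exposed.

#' Detect the rupture event of a pulling trace
#'
#' Applies the documented identification rule: both series are smoothed
#' with a 20 ps running average, the crossing time is the first time the
#' core SASA exceeds `threshold` (50 A^2 by default) and stays above it
#' for two consecutive records, and the peak force is the highest smoothed
#' force within a `window` (400 ps) wide search window centered on the
#' crossing.  Ties take the earliest peak time.  When the SASA never
#' crosses the threshold a no-event result is returned (test with
#' [hasEvent()]); that is a legitimate outcome, not an error.
#'
#' @param forceSeries [Series-class] of applied force.
#' @param sasaSeries [Series-class] of core SASA (A^2); resampled onto the
#'   force time base by nearest time when the grids differ.
#' @param threshold A^2 (default 50).
#' @param window full width of the peak-search window, ps (default 400).
#' @param smoothWindow running-average window applied to both series
#'   before the rule, ps (default 20; 0 disables smoothing).
#' @param forceUnit unit of `forceSeries` values, `"pN"` or
#'   `"kcalmolA"`.
#' @param persistence consecutive records the SASA must stay above the
#'   threshold (default 2, guarding against single-record noise).
#' @return a [RuptureEvent-class].
#' @export
detectRupture <- function(forceSeries, sasaSeries, threshold = 50,
                          window = 400, smoothWindow = 20,
                          forceUnit = c("pN", "kcalmolA"),
                          persistence = 2L) {
  stopifnot(is(forceSeries, "Series"), is(sasaSeries, "Series"))
  forceUnit <- match.arg(forceUnit)
  if (length(forceSeries@times) == 0 || length(sasaSeries@times) == 0)
    oxStop("empty series", "oxfold_domain_error")
  t <- forceSeries@times
  ## nearest-time resampling of the SASA onto the force time base
  sVals <- sasaSeries@values[vapply(t, function(ti)
    which.min(abs(sasaSeries@times - ti)), integer(1))]
  f <- forceSeries@values
  if (smoothWindow > 0) {
    f <- runningAverage(newSeries(t, f), smoothWindow)@values
    sVals <- runningAverage(newSeries(t, sVals), smoothWindow)@values
  }
  above <- sVals > threshold
  crossIdx <- NA_integer_
  run <- rle(above)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1L
  ok <- which(run$values & run$lengths >= persistence)
  if (length(ok)) crossIdx <- starts[ok[1]]
  if (is.na(crossIdx))
    return(new("RuptureEvent", event = FALSE, crossingTime = NA_real_,
               peakTime = NA_real_, peakForce = NA_real_,
               peakForcePN = NA_real_, window = window,
               threshold = threshold))
  tc <- t[crossIdx]
  inWin <- which(t >= tc - window / 2 - 1e-9 & t <= tc + window / 2 + 1e-9)
  peakIdx <- inWin[which.max(f[inWin])]   # which.max: earliest on ties
  fk <- if (forceUnit == "pN") f[peakIdx] / pnPerKcalMolA else f[peakIdx]
  new("RuptureEvent", event = TRUE, crossingTime = tc,
      peakTime = t[peakIdx], peakForce = fk,
      peakForcePN = fk * pnPerKcalMolA, window = window,
      threshold = threshold)
}

#' Rupture event of a pulling run
#'
#' Convenience wrapper extracting the force and core-SASA series of a
#' [PullingTrace-class] and running [detectRupture()].
#'
#' @param trace a [PullingTrace-class].
#' @param ... passed to [detectRupture()].
#' @return a [RuptureEvent-class].
#' @export
traceRupture <- function(trace, ...) {
  detectRupture(traceSeries(trace, "force_pN"),
                traceSeries(trace, "core_sasa_A2"), forceUnit = "pN", ...)
}
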
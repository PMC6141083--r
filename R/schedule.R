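## Lambda schedules for alchemical transformations.

#' Build a lambda schedule
#'
#' Uniformly spaced coupling states from 0 (unoxidized methionine) to 1
#' (methionine sulfoxide).  The default protocol shape is 100 states of
#' 100 ps each (10 ns total), the first half of every window spent on
#' equilibration and the second half on data collection.
#'
#' @param nWindows number of lambda states (>= 2).
#' @param windowLength ps per state (default 100).
#' @param equilibrationFraction fraction of each window discarded as
#'   equilibration, in [0, 1) (default 0.5).
#' @return a [LambdaSchedule-class].
#' @export
makeSchedule <- function(nWindows = 100L, windowLength = 100,
                         equilibrationFraction = 0.5) {
  if (nWindows < 2)
    oxStop("need at least 2 lambda states", "oxfold_domain_error")
  if (equilibrationFraction < 0 || equilibrationFraction >= 1)
    oxStop("equilibrationFraction must be in [0, 1)", "oxfold_domain_error")
  if (windowLength <= 0)
    oxStop("windowLength must be > 0", "oxfold_domain_error")
  new("LambdaSchedule", nWindows = as.integer(nWindows),
      windowLength = windowLength,
      equilibrationFraction = equilibrationFraction,
      lambdas = seq(0, 1, length.out = nWindows))
}
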
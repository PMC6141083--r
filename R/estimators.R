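## Free-energy estimators: exponential averaging (Zwanzig) and the Bennett
## acceptance ratio.  All internal math is in reduced units (delta-U / kT);
## results are reported in kcal/mol.

#' Exponential-averaging (Zwanzig) free-energy estimate
#'
#' Per window \eqn{\Delta G = -k_B T \ln \langle e^{-\Delta U / k_B T}
#' \rangle} over the chosen direction's samples (sign-adjusted so that the
#' backward direction also estimates the forward delta-G); windows are
#' summed.  One-directional and biased at poor overlap, so it brackets the
#' Bennett estimate: forward-EXP from above, backward-EXP from below (in
#' expectation).  The standard error comes from a block bootstrap within
#' each window.
#'
#' @param work a [WorkData-class].
#' @param direction `"forward"` or `"backward"`.
#' @param nBlocks blocks per window for the bootstrap (default 20).
#' @param nBoot bootstrap replicates (default 200).
#' @param bootSeed seed for the bootstrap resampling (kept separate from
#'   analysis seeds; the global RNG stream is left untouched).
#' @return a [FreeEnergyEstimate-class].
#' @export
expEstimate <- function(work, direction = c("forward", "backward"),
                        nBlocks = 20L, nBoot = 200L, bootSeed = 1L) {
  stopifnot(is(work, "WorkData"))
  direction <- match.arg(direction)
  samples <- if (direction == "forward") work@forward else work@backward
  if (!length(samples))
    oxStop(paste("no", direction, "samples"), "oxfold_domain_error")
  kt <- kT(work@temperature)
  sign <- if (direction == "forward") 1 else -1
  perWindow <- function(w) -kt * logMeanExp(-w / kt)
  dgW <- vapply(samples, perWindow, numeric(1))
  dg <- sign * sum(dgW)
  se <- withLocalSeed(bootSeed, {
    boots <- vapply(seq_len(nBoot), function(b) {
      sum(vapply(samples, function(w) {
        n <- length(w)
        nb <- min(nBlocks, n)
        id <- cut(seq_len(n), nb, labels = FALSE)
        keep <- unlist(split(w, id)[sample.int(nb, nb, replace = TRUE)],
                       use.names = FALSE)
        perWindow(keep)
      }, numeric(1)))
    }, numeric(1))
    sd(boots)
  })
  new("FreeEnergyEstimate", deltaG = dg, standardError = se,
      method = paste0("EXP_", direction), nWindows = length(samples),
      temperature = work@temperature)
}

## Solve the Bennett self-consistent equation for one window, reduced
## units.  wF, wB are forward and backward delta-U samples.  Returns the
## root C (= window delta-G when n-ratio shift M is folded in as below)
## and the asymptotic variance.
barWindow <- function(wF, wB, tolerance) {
  nF <- length(wF); nB <- length(wB)
  M <- log(nF / nB)
  fermi <- function(x) 1 / (1 + exp(x))
  ## g is monotone increasing in C; its root is the window delta-G
  g <- function(C) sum(fermi(M + wF - C)) - sum(fermi(wB + C - M))
  ## bracket by doubling around the forward-EXP initial guess
  C0 <- -logMeanExp(-wF)
  lo <- C0 - 1; hi <- C0 + 1
  for (k in 1:60) {
    if (g(lo) < 0) break
    lo <- C0 - 2^k
  }
  for (k in 1:60) {
    if (g(hi) > 0) break
    hi <- C0 + 2^k
  }
  if (g(lo) >= 0 || g(hi) <= 0)
    oxStop("no root for the Bennett equation; forward/backward overlap is insufficient (use more windows)",
           "oxfold_overlap_error")
  C <- uniroot(g, c(lo, hi), tol = tolerance)$root
  fF <- fermi(M + wF - C)
  fB <- fermi(wB + C - M)
  varC <- (mean(fF^2) / mean(fF)^2 - 1) / nF +
    (mean(fB^2) / mean(fB)^2 - 1) / nB
  list(dg = C, var = max(0, varC))
}

#' Bennett acceptance ratio free-energy estimate
#'
#' Per window the estimate solves Bennett's self-consistent equation
#' \deqn{\sum_i f(\beta(\Delta U^F_i - C)) = \sum_j f(\beta(\Delta U^B_j + C))}
#' (f the Fermi function, with the sample-count shift \eqn{\ln(n_F/n_B)}
#' folded in), by bracket expansion around the forward-EXP guess and
#' bisection/Brent refinement.  Window delta-Gs are summed; Bennett's
#' asymptotic variance is summed in quadrature (samples treated as
#' independent; replicate-level SEM is the error bar to quote across
#' repeated runs).
#'
#' @param work a [WorkData-class] with both directions present.
#' @param tolerance root tolerance in kT units (default 1e-8).
#' @return a [FreeEnergyEstimate-class].
#' @export
barEstimate <- function(work, tolerance = 1e-8) {
  stopifnot(is(work, "WorkData"))
  if (!length(work@forward) || !length(work@backward))
    oxStop("BAR needs forward and backward samples in every window",
           "oxfold_domain_error")
  kt <- kT(work@temperature)
  res <- mapply(function(wF, wB) barWindow(wF / kt, wB / kt, tolerance),
                work@forward, work@backward, SIMPLIFY = FALSE)
  dg <- kt * sum(vapply(res, `[[`, numeric(1), "dg"))
  se <- kt * sqrt(sum(vapply(res, `[[`, numeric(1), "var")))
  new("FreeEnergyEstimate", deltaG = dg, standardError = se,
      method = "BAR", nWindows = length(res),
      temperature = work@temperature)
}
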
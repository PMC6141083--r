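## Metropolis sampling of energy-difference (delta-U) data over a lambda
## schedule, in the forward and backward direction.

#' Sample per-window energy differences for a toy alchemical system
#'
#' Forward pass: the system is simulated at each lambda state in turn
#' (carrying the configuration over), the first `equilibrationFraction`
#' of each window discarded, and \eqn{\Delta U = U(x, \lambda_{i+1}) -
#' U(x, \lambda_i)} recorded at every collection step.  The backward pass
#' starts from the configuration reached at the end of the forward
#' transformation (mirroring the forward/backward protocol of the
#' oxidation FEP runs) and walks the states in reverse, recording
#' \eqn{U(x, \lambda_i) - U(x, \lambda_{i+1})} at state
#' \eqn{\lambda_{i+1}}.  Deterministic for a fixed seed.
#'
#' @param system a [ToyAlchemicalSystem-class].
#' @param schedule a [LambdaSchedule-class].
#' @param seed integer RNG seed.
#' @param stepsPerPs Metropolis steps that one ps of window time maps to
#'   (default 20; a window of 100 ps then maps to 2000 steps).
#' @param thin record one delta-U sample every `thin` collection steps
#'   (default 10).  Thinning keeps the recorded samples close to
#'   independent, which the Bennett variance formula assumes.
#' @param backwardStart `"forward_end"` (the stated protocol) or
#'   `"independent"` (fresh equilibration at lambda = 1, for diagnostics).
#' @return a [WorkData-class] in kcal/mol.
#' @export
sampleWindows <- function(system, schedule, seed, stepsPerPs = 20,
                          thin = 10L,
                          backwardStart = c("forward_end", "independent")) {
  stopifnot(is(system, "ToyAlchemicalSystem"),
            is(schedule, "LambdaSchedule"))
  backwardStart <- match.arg(backwardStart)
  lam <- schedule@lambdas
  nTrans <- length(lam) - 1
  nSteps <- max(2L, round(schedule@windowLength * stepsPerPs))
  nEquil <- round(nSteps * schedule@equilibrationFraction)
  nCollect <- nSteps - nEquil
  if (nCollect < 1)
    oxStop("schedule leaves no collection phase", "oxfold_domain_error")
  thin <- max(1L, min(as.integer(thin), nCollect))
  beta <- 1 / kT(system@temperature)
  U <- system@energy
  step <- system@stepSize

  withLocalSeed(seed, {
    mcmc <- function(x, lamHere, n, collectLam = NULL) {
      ## pre-draw proposals and uniforms for speed
      prop <- rnorm(n, 0, step)
      us <- runif(n)
      du <- if (is.null(collectLam)) NULL else
        numeric(length(seq.int(thin, n, by = thin)))
      uCur <- U(x, lamHere)
      nAcc <- 0L
      k <- 0L
      for (s in seq_len(n)) {
        xNew <- x + prop[s]
        uNew <- U(xNew, lamHere)
        if (us[s] < exp(-beta * (uNew - uCur))) {
          x <- xNew; uCur <- uNew; nAcc <- nAcc + 1L
        }
        if (!is.null(du) && s %% thin == 0L) {
          k <- k + 1L
          du[k] <- U(x, collectLam) - uCur
        }
      }
      list(x = x, du = du, acc = nAcc / n)
    }
    checkHealth <- function(acc, i) {
      if (acc < 0.01)
        oxStop(sprintf(
          "Metropolis acceptance %.2f%% in window %d; adjust stepSize",
          100 * acc, i), "oxfold_sampler_health_error")
    }

    forward <- vector("list", nTrans)
    x <- 0
    ## settle into the first state before the schedule proper
    x <- mcmc(x, lam[1], nSteps)$x
    for (i in seq_len(nTrans)) {
      x <- mcmc(x, lam[i], nEquil)$x
      r <- mcmc(x, lam[i], nCollect, collectLam = lam[i + 1])
      checkHealth(r$acc, i)
      forward[[i]] <- r$du
      x <- r$x
    }
    ## land in the final state, then walk back
    if (backwardStart == "independent") x <- 0
    x <- mcmc(x, lam[nTrans + 1], nSteps)$x
    backward <- vector("list", nTrans)
    for (i in rev(seq_len(nTrans))) {
      x <- mcmc(x, lam[i + 1], nEquil)$x
      r <- mcmc(x, lam[i + 1], nCollect, collectLam = lam[i])
      checkHealth(r$acc, i)
      backward[[i]] <- r$du
      x <- r$x
    }
    new("WorkData", forward = forward, backward = backward,
        lambdas = lam, temperature = system@temperature)
  })
}

#' Run a full alchemical estimate on a toy system
#'
#' Composition [sampleWindows()] then [barEstimate()]: samples forward and
#' backward energy differences over the schedule and combines them with
#' the Bennett acceptance ratio.
#'
#' @inheritParams sampleWindows
#' @param ... passed to [sampleWindows()].
#' @return a [FreeEnergyEstimate-class].
#' @export
runAlchemical <- function(system, schedule, seed, ...) {
  work <- sampleWindows(system, schedule, seed, ...)
  barEstimate(work)
}
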
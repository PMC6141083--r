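## Constant-velocity pulling: protocol parameters, the Langevin run, and
## the Hookean spring force.

#' Pulling protocol parameters
#'
#' Defaults follow the steered protocol for this system: spring stiffness
#' 2 kcal/mol/A^2 (the conventional reading of "2 kcal/mol" for an SMD
#' spring), constant velocity 5 A/ns, 300 K, records every 10 ps.  The
#' 5 fs step is comfortable for the toy model's soft beads (the stiffest
#' mode has a ~240 fs period).  The first bead is held fixed and the
#' chain terminus is pulled.
#'
#' @param springK kcal/mol/A^2.
#' @param velocity A/ns.
#' @param fixedAtom,pulledAtom bead indices.
#' @param temperature K.
#' @param friction Langevin friction, ps^-1.
#' @param dt fs.
#' @param duration ns.
#' @param recordInterval ps.
#' @return a [PullParams-class].
#' @export
pullParams <- function(springK = 2, velocity = 5, fixedAtom = 1L,
                       pulledAtom = 22L, temperature = 300, friction = 1,
                       dt = 5, duration = 4, recordInterval = 10) {
  new("PullParams", springK = springK, velocity = velocity,
      fixedAtom = as.integer(fixedAtom), pulledAtom = as.integer(pulledAtom),
      temperature = temperature, friction = friction, dt = dt,
      duration = duration, recordInterval = recordInterval)
}

#' Run a constant-velocity pulling simulation
#'
#' Langevin (BAOAB) dynamics of the toy model with the first bead
#' restrained and a virtual spring connecting the pulled bead to a dummy
#' point moving at constant velocity along the initial fixed-to-pulled
#' axis.  The applied force follows Hook's law, F = k * extension, at
#' every record.  The core SASA column is computed per recorded frame
#' with [sasaFrame()] on the model's core set.
#'
#' @param model a [ToyModel-class].
#' @param pull a [PullParams-class].
#' @param seed integer seed for the thermal noise (a run is deterministic
#'   given model, pull and seed).
#' @param sasaPoints quadrature points for the per-frame core SASA
#'   (default 240; the built-state value is quadrature-stable well below
#'   the rupture threshold).
#' @param coreSasa set FALSE to skip the per-frame SASA (fills NA).
#' @return list with `trace` (a [PullingTrace-class]) and `trajectory`
#'   (a [Trajectory-class] of recorded bead frames).
#' @export
runCVPulling <- function(model, pull = pullParams(), seed = 1L,
                         sasaPoints = 240L, coreSasa = TRUE) {
  stopifnot(is(model, "ToyModel"), is(pull, "PullParams"))
  if (pull@fixedAtom > nrow(model@positions))
    oxStop("fixedAtom out of range", "oxfold_domain_error")
  res <- cvPullCore(
    model@positions, model@bonds$i, model@bonds$j, model@bonds$k,
    model@bonds$r0, model@contacts$i, model@contacts$j,
    model@contacts$eps, model@contacts$r0,
    repEps = 1.0, repSigma = 2 * model@beadRadius,
    mass = model@mass, fixedIdx = pull@fixedAtom,
    pulledIdx = pull@pulledAtom, springK = pull@springK,
    velocityApNs = pull@velocity, temperature = pull@temperature,
    frictionPs = pull@friction, dtFs = pull@dt, durationNs = pull@duration,
    recordIntervalPs = pull@recordInterval, seed = as.integer(seed),
    thermostat = pull@friction > 0)
  if (isTRUE(res$unstable))
    oxStop("integrator blew up (|coordinate| > 10^4 A); use a smaller dt",
           "oxfold_instability_error")
  nr <- as.integer(res$n_recorded)
  frames <- res$frames[seq_len(nr), , drop = FALSE]
  n <- nrow(model@positions)
  structures <- lapply(seq_len(nr), function(k)
    toyModelStructure(model, matrix(frames[k, ], n, 3, byrow = TRUE)))
  core <- if (coreSasa)
    vapply(structures, function(st)
      sasaFrame(st, model@coreSet, nPoints = sasaPoints)@groupTotal,
      numeric(1))
  else rep(NA_real_, nr)
  d <- data.frame(
    time_ps = res$time_ps, dummy_A = res$dummy_A, pulled_A = res$pulled_A,
    extension_A = res$extension_A, force_kcalmolA = res$force_kcalmolA,
    force_pN = res$force_kcalmolA * pnPerKcalMolA, core_sasa_A2 = core,
    kinetic_kcalmol = res$kinetic_kcalmol,
    potential_kcalmol = res$potential_kcalmol)
  trace <- new("PullingTrace", data = d, springK = pull@springK)
  traj <- new("Trajectory", frames = structures,
              frameInterval = pull@recordInterval)
  list(trace = trace, trajectory = traj)
}

#' Hookean spring force with unit mirror
#'
#' F = k * extension, the extension being the signed projection of
#' (dummy - pulled) onto the pull axis; scalar positions are taken as
#' projections directly.  Reported in kcal/mol/A and pN
#' (1 kcal/mol/A = 69.4786 pN).
#'
#' @param dummyPosition,pulledPosition scalars (projections, A) or
#'   3-vectors.
#' @param springK kcal/mol/A^2 (>= 0).
#' @param axis pull axis for 3-vector input (normalized internally).
#' @return named numeric c(kcalmolA =, pN =).
#' @export
springForce <- function(dummyPosition, pulledPosition, springK,
                        axis = c(1, 0, 0)) {
  stopifnot(springK >= 0)
  if (length(dummyPosition) == 3) {
    a <- axis / sqrt(sum(axis^2))
    ext <- sum((dummyPosition - pulledPosition) * a)
  } else {
    ext <- dummyPosition - pulledPosition
  }
  f <- springK * ext
  c(kcalmolA = f, pN = f * pnPerKcalMolA)
}

#' Write / read a pulling trace as TSV
#'
#' Columns time_ps, dummy_A, pulled_A, extension_A, force_kcalmolA,
#' force_pN, core_sasa_A2 (energy bookkeeping columns are carried along
#' when present); a header comment records the spring stiffness.
#'
#' @param trace a [PullingTrace-class].
#' @param path TSV file.
#' @return `path` invisibly (write) or a [PullingTrace-class] (read).
#' @export
writeTraceTSV <- function(trace, path) {
  stopifnot(is(trace, "PullingTrace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# spring_k_kcalmolA2=%g", trace@springK), con)
  write.table(trace@data, con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeTraceTSV
#' @export
readTraceTSV <- function(path) {
  first <- readLines(path, n = 1)
  k <- 2
  m <- regmatches(first, regexec("spring_k_kcalmolA2=([0-9.eE+-]+)", first))[[1]]
  if (length(m) == 2) k <- as.numeric(m[2])
  d <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  new("PullingTrace", data = d, springK = k)
}

#' Extract a column of a pulling trace as a Series
#'
#' @param trace a [PullingTrace-class].
#' @param column trace column name, e.g. `"force_pN"` or
#'   `"core_sasa_A2"`.
#' @return a [Series-class].
#' @export
traceSeries <- function(trace, column) {
  d <- traceData(trace)
  if (!column %in% names(d))
    oxStop(paste("no trace column", column), "oxfold_domain_error")
  newSeries(d$time_ps, d[[column]], column)
}
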
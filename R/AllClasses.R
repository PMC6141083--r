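## S4 class definitions and validity methods for the package's containers.

REQUIRED_ATOM_COLS <- c("serial", "name", "element", "resname", "resid",
                        "chain", "x", "y", "z", "radius", "charge",
                        "ljEpsilon", "ljRminHalf")

#' Structure: an ordered set of atoms
#'
#' A molecular model: one conformation of a set of atoms with residue and
#' chain bookkeeping and optional per-atom nonbonded parameters (radius,
#' partial charge, Lennard-Jones well depth and half-minimum distance).
#' Coordinates are Angstrom.  Parameter columns are `NA` until
#' [assignParams()] populates them (generators may also set them directly).
#'
#' @slot atoms data.frame with columns serial, name, element, resname,
#'   resid, chain, x, y, z, radius, charge, ljEpsilon, ljRminHalf.
#' @slot modelId integer model number (1 for single-model files).
#' @slot provenance free-text origin of the model.
#' @export
setClass("Structure", representation(
  atoms = "data.frame", modelId = "integer", provenance = "character"))

setValidity("Structure", function(object) {
  a <- object@atoms
  missing <- setdiff(REQUIRED_ATOM_COLS, names(a))
  if (length(missing))
    return(paste("missing atom columns:", paste(missing, collapse = ", ")))
  if (nrow(a) == 0) return("structure has no atoms")
  if (!all(is.finite(as.matrix(a[, c("x", "y", "z")]))))
    return("non-finite atom coordinates")
  if (anyDuplicated(a$serial)) return("duplicate atom serials within model")
  key <- paste(a$chain, a$resid, a$name)
  if (anyDuplicated(key))
    return("duplicate (chain, resid, name) triple within model")
  rad <- a$radius[!is.na(a$radius)]
  if (length(rad) && any(rad <= 0)) return("atom radius must be > 0 when set")
  ## residues must be contiguous runs of atoms
  rkey <- paste(a$chain, a$resid)
  runs <- rle(rkey)$values
  if (anyDuplicated(runs)) return("residues are not contiguous runs of atoms")
  TRUE
})

#' Trajectory: ordered frames sharing one topology
#'
#' @slot frames list of [Structure-class] objects with identical atom count
#'   and ordering.
#' @slot frameInterval time between frames, ps.
#' @export
setClass("Trajectory", representation(
  frames = "list", frameInterval = "numeric"))

setValidity("Trajectory", function(object) {
  if (length(object@frames) == 0) return("trajectory has no frames")
  if (!all(vapply(object@frames, is, logical(1), "Structure")))
    return("frames must all be Structure objects")
  n <- vapply(object@frames, function(f) nrow(f@atoms), integer(1))
  if (length(unique(n)) != 1)
    return("frames differ in atom count")
  nm0 <- object@frames[[1]]@atoms$name
  same <- vapply(object@frames, function(f) identical(f@atoms$name, nm0),
                 logical(1))
  if (!all(same)) return("frames differ in atom ordering")
  if (length(object@frameInterval) != 1 || object@frameInterval <= 0)
    return("frameInterval must be a single positive number (ps)")
  TRUE
})

#' AtomSet: a selection of atoms within a structure
#'
#' Holds 1-based atom positions into a fixed universe (a [Structure-class]),
#' so that complements are well defined.
#'
#' @slot indices integer atom positions (1-based, sorted, unique).
#' @slot universeSize number of atoms in the parent structure.
#' @slot label free-text description of the selection.
#' @export
setClass("AtomSet", representation(
  indices = "integer", universeSize = "integer", label = "character"))

setValidity("AtomSet", function(object) {
  i <- object@indices
  if (length(i) == 0) return("empty atom set")
  if (any(i < 1L) || any(i > object@universeSize))
    return("atom indices out of bounds")
  if (anyDuplicated(i)) return("duplicate atom indices")
  TRUE
})

#' ParamTable: nonbonded parameter lookup
#'
#' Rows keyed by (residue name, atom name); residue name `"*"` marks
#' fallback rows matched by atom name, then by element symbol.
#'
#' @slot table data.frame with columns residue_name, atom_name, radius_A,
#'   charge_e, lj_epsilon, lj_rmin_half.
#' @export
setClass("ParamTable", representation(table = "data.frame"))

setValidity("ParamTable", function(object) {
  t <- object@table
  need <- c("residue_name", "atom_name", "radius_A", "charge_e",
            "lj_epsilon", "lj_rmin_half")
  missing <- setdiff(need, names(t))
  if (length(missing))
    return(paste("missing columns:", paste(missing, collapse = ", ")))
  if (any(t$radius_A <= 0)) return("radii must be > 0")
  if (any(t$lj_epsilon < 0)) return("lj_epsilon must be >= 0")
  TRUE
})

#' Series: a time series of one scalar quantity
#'
#' @slot times ps, strictly increasing.
#' @slot values unit-bearing scalars (unit recorded in `label`).
#' @slot label description, conventionally "quantity_unit".
#' @export
setClass("Series", representation(
  times = "numeric", values = "numeric", label = "character"))

setValidity("Series", function(object) {
  if (length(object@times) != length(object@values))
    return("times and values differ in length")
  if (length(object@times) == 0) return("empty series")
  if (any(diff(object@times) <= 0)) return("times must be strictly increasing")
  TRUE
})

#' HBondCriteria: geometric hydrogen-bond definition
#'
#' A donor-H / acceptor pair qualifies when the H...acceptor distance is at
#' most `maxHAcceptorDistance` and the donor-H...acceptor angle is at least
#' `minDonorAngle` (both boundaries inclusive).  Defaults are the 2.7 A /
#' 120 degree criteria used for methionine-sulfoxide hydration analysis.
#'
#' @slot maxHAcceptorDistance Angstrom.
#' @slot minDonorAngle degrees.
#' @export
setClass("HBondCriteria", representation(
  maxHAcceptorDistance = "numeric", minDonorAngle = "numeric"))

setValidity("HBondCriteria", function(object) {
  if (object@maxHAcceptorDistance <= 0) return("distance cutoff must be > 0")
  if (object@minDonorAngle <= 0 || object@minDonorAngle > 180)
    return("angle cutoff must be in (0, 180]")
  TRUE
})

#' SASAResult: per-atom and group solvent accessible surface area
#'
#' @slot perAtom named numeric, A^2 per group atom (names = atom indices).
#' @slot groupTotal A^2.
#' @slot probeRadius A.
#' @slot nPoints quadrature points per atom.
#' @export
setClass("SASAResult", representation(
  perAtom = "numeric", groupTotal = "numeric",
  probeRadius = "numeric", nPoints = "integer"))

setValidity("SASAResult", function(object) {
  if (any(object@perAtom < 0) || object@groupTotal < 0)
    return("SASA values must be >= 0")
  if (abs(sum(object@perAtom) - object@groupTotal) > 1e-6)
    return("groupTotal must equal the sum of per-atom values")
  TRUE
})

#' EnergyPair: switched nonbonded interaction energy between two groups
#'
#' @slot electrostatic kcal/mol.
#' @slot vanDerWaals kcal/mol.
#' @slot cutoff A.
#' @slot switchOn A.
#' @export
setClass("EnergyPair", representation(
  electrostatic = "numeric", vanDerWaals = "numeric",
  cutoff = "numeric", switchOn = "numeric"))

setValidity("EnergyPair", function(object) {
  if (!is.finite(object@electrostatic) || !is.finite(object@vanDerWaals))
    return("energies must be finite")
  TRUE
})

#' LambdaSchedule: alchemical coupling schedule
#'
#' `lambdas` are the coupling states visited (0 = unoxidized endpoint,
#' 1 = sulfoxide endpoint); each state is simulated for `windowLength` ps,
#' the first `equilibrationFraction` of which is discarded as
#' equilibration.
#'
#' @slot nWindows number of lambda states.
#' @slot windowLength ps per state.
#' @slot equilibrationFraction fraction in [0, 1).
#' @slot lambdas ordered values from 0 to 1.
#' @export
setClass("LambdaSchedule", representation(
  nWindows = "integer", windowLength = "numeric",
  equilibrationFraction = "numeric", lambdas = "numeric"))

setValidity("LambdaSchedule", function(object) {
  l <- object@lambdas
  if (length(l) != object@nWindows) return("lambdas length != nWindows")
  if (l[1] != 0 || l[length(l)] != 1) return("lambdas must run from 0 to 1")
  if (any(diff(l) <= 0)) return("lambdas must be strictly increasing")
  if (object@equilibrationFraction < 0 || object@equilibrationFraction >= 1)
    return("equilibrationFraction must be in [0, 1)")
  if (object@windowLength <= 0) return("windowLength must be > 0")
  TRUE
})

#' WorkData: per-window energy-difference samples
#'
#' Forward samples of window i are \eqn{u(\lambda_{i+1}) - u(\lambda_i)}
#' collected at state \eqn{\lambda_i}; backward samples are
#' \eqn{u(\lambda_i) - u(\lambda_{i+1})} collected at state
#' \eqn{\lambda_{i+1}}.  All values kcal/mol, post-equilibration only.
#'
#' @slot forward list of numeric vectors, one per transition.
#' @slot backward list of numeric vectors, one per transition (may be empty
#'   list when only one direction was sampled).
#' @slot lambdas the lambda states bounding the transitions.
#' @slot temperature K.
#' @export
setClass("WorkData", representation(
  forward = "list", backward = "list", lambdas = "numeric",
  temperature = "numeric"))

setValidity("WorkData", function(object) {
  nw <- length(object@lambdas) - 1
  if (nw < 1) return("need at least two lambda states")
  if (length(object@forward) != nw && length(object@forward) != 0)
    return("forward list length must equal number of transitions")
  if (length(object@backward) != nw && length(object@backward) != 0)
    return("backward list length must equal number of transitions")
  cnt <- vapply(c(object@forward, object@backward), length, integer(1))
  if (length(cnt) && any(cnt == 0)) return("empty sample vector in a window")
  if (object@temperature <= 0) return("temperature must be > 0")
  TRUE
})

#' FreeEnergyEstimate: a delta-G with its standard error
#'
#' @slot deltaG kcal/mol.
#' @slot standardError kcal/mol.
#' @slot method one of "EXP_forward", "EXP_backward", "BAR".
#' @slot nWindows number of transitions combined.
#' @slot temperature K.
#' @export
setClass("FreeEnergyEstimate", representation(
  deltaG = "numeric", standardError = "numeric", method = "character",
  nWindows = "integer", temperature = "numeric"))

setValidity("FreeEnergyEstimate", function(object) {
  if (object@standardError < 0) return("standardError must be >= 0")
  if (!object@method %in% c("EXP_forward", "EXP_backward", "BAR"))
    return("unknown method")
  TRUE
})

#' DDGResult: thermodynamic-cycle delta-delta-G of folding
#'
#' `ddg = deltaG(folded) - deltaG(unfolded)`; positive values mean the
#' oxidation is thermodynamically unfavorable for folding.
#'
#' @slot folded,unfolded [FreeEnergyEstimate-class] legs.
#' @slot ddg kcal/mol.
#' @slot standardError kcal/mol (quadrature of the two legs).
#' @export
setClass("DDGResult", representation(
  folded = "FreeEnergyEstimate", unfolded = "FreeEnergyEstimate",
  ddg = "numeric", standardError = "numeric"))

setValidity("DDGResult", function(object) {
  if (abs(object@ddg -
          (object@folded@deltaG - object@unfolded@deltaG)) > 1e-12)
    return("ddg must equal folded - unfolded exactly")
  se <- sqrt(object@folded@standardError^2 + object@unfolded@standardError^2)
  if (abs(object@standardError - se) > 1e-12)
    return("standardError must be the quadrature of the two legs")
  TRUE
})

#' ToyAlchemicalSystem: a one-dimensional alchemical test system
#'
#' A potential family U(x, lambda) with Metropolis sampler settings and,
#' when available, a closed-form (or quadrature-exact) delta-G between the
#' endpoints.
#'
#' @slot energy function(x, lambda) -> kcal/mol, vectorized in x.
#' @slot stepSize Metropolis proposal standard deviation, A.
#' @slot temperature K.
#' @slot closedFormDg kcal/mol, or NA when no reference value exists.
#' @slot label description.
#' @export
setClass("ToyAlchemicalSystem", representation(
  energy = "function", stepSize = "numeric", temperature = "numeric",
  closedFormDg = "numeric", label = "character"))

#' ToyModel: coarse-grained two-block chain for pulling simulations
#'
#' A bead chain of a "body" block shielding a hydrophobic core plus a
#' docked "helix" block, standing in for a force-sensing domain whose
#' unfolding begins with undocking of its C-terminal helix.  Oxidation is
#' modelled by scaling the well depth of the oxidizable (helix-docking)
#' native contacts.
#'
#' @slot positions n x 3 matrix, A.
#' @slot types character, "body" or "helix" per bead.
#' @slot bonds data.frame (i, j, k, r0): harmonic bonds, k kcal/mol/A^2.
#' @slot contacts data.frame (i, j, eps, r0, oxidizable): 12-10 native
#'   contacts, eps kcal/mol.
#' @slot coreSet [AtomSet-class]: the buried-core beads whose SASA reports
#'   rupture.
#' @slot beadRadius A.
#' @slot mass amu per bead.
#' @slot oxidationFactor factor applied to oxidizable contact eps.
#' @export
setClass("ToyModel", representation(
  positions = "matrix", types = "character", bonds = "data.frame",
  contacts = "data.frame", coreSet = "AtomSet", beadRadius = "numeric",
  mass = "numeric", oxidationFactor = "numeric"))

setValidity("ToyModel", function(object) {
  n <- nrow(object@positions)
  if (ncol(object@positions) != 3) return("positions must be n x 3")
  if (length(object@types) != n) return("types length mismatch")
  if (nrow(object@bonds) < n - 1) return("chain is not connected")
  b <- object@bonds
  ## consecutive beads must be bonded (chain connectivity)
  chain <- paste(pmin(b$i, b$j), pmax(b$i, b$j))
  need <- paste(seq_len(n - 1), seq_len(n - 1) + 1)
  if (!all(need %in% chain)) return("chain is not connected")
  if (nrow(object@contacts) && any(object@contacts$eps <= 0))
    return("contact eps must be > 0")
  if (object@beadRadius <= 0) return("beadRadius must be > 0")
  TRUE
})

#' PullParams: constant-velocity pulling protocol
#'
#' Defaults mirror the standard steered protocol for this system: a
#' virtual spring of stiffness 2 kcal/mol/A^2 pulled at 5 A/ns, Langevin
#' dynamics at 300 K with a 2 fs time step, records every 10 ps.
#'
#' @slot springK kcal/mol/A^2.
#' @slot velocity A/ns.
#' @slot fixedAtom,pulledAtom bead indices (1-based).
#' @slot temperature K.
#' @slot friction ps^-1.
#' @slot dt fs.
#' @slot duration ns.
#' @slot recordInterval ps.
#' @export
setClass("PullParams", representation(
  springK = "numeric", velocity = "numeric", fixedAtom = "integer",
  pulledAtom = "integer", temperature = "numeric", friction = "numeric",
  dt = "numeric", duration = "numeric", recordInterval = "numeric"))

setValidity("PullParams", function(object) {
  if (object@springK < 0) return("springK must be >= 0")
  if (object@velocity < 0) return("velocity must be >= 0")
  if (object@dt <= 0) return("dt must be > 0")
  if (object@duration <= 0) return("duration must be > 0")
  if (object@fixedAtom == object@pulledAtom)
    return("fixedAtom and pulledAtom must differ")
  TRUE
})

#' PullingTrace: recorded time series of a pulling run
#'
#' @slot data data.frame with columns time_ps, dummy_A, pulled_A,
#'   extension_A, force_kcalmolA, force_pN, core_sasa_A2 (and energy
#'   bookkeeping columns kinetic_kcalmol, potential_kcalmol).
#' @slot springK kcal/mol/A^2 (so force = springK * extension holds by
#'   construction at every record).
#' @export
setClass("PullingTrace", representation(
  data = "data.frame", springK = "numeric"))

setValidity("PullingTrace", function(object) {
  d <- object@data
  need <- c("time_ps", "dummy_A", "pulled_A", "extension_A",
            "force_kcalmolA", "force_pN", "core_sasa_A2")
  missing <- setdiff(need, names(d))
  if (length(missing))
    return(paste("missing trace columns:", paste(missing, collapse = ", ")))
  if (any(diff(d$time_ps) <= 0)) return("times must be increasing")
  if (max(abs(d$force_kcalmolA - object@springK * d$extension_A)) > 1e-6)
    return("force must equal springK * extension at every record")
  TRUE
})

#' RuptureEvent: force peak coupled to core exposure
#'
#' @slot event logical; FALSE marks the documented no-event result (the
#'   SASA series never exceeded the threshold).
#' @slot crossingTime ps: first time the (smoothed) core SASA exceeds the
#'   threshold persistently.
#' @slot peakTime ps: argmax of force within the search window (earliest
#'   on ties).
#' @slot peakForce kcal/mol/A.
#' @slot peakForcePN pN.
#' @slot window ps (full width of the peak-search window).
#' @slot threshold A^2.
#' @export
setClass("RuptureEvent", representation(
  event = "logical", crossingTime = "numeric", peakTime = "numeric",
  peakForce = "numeric", peakForcePN = "numeric", window = "numeric",
  threshold = "numeric"))

setValidity("RuptureEvent", function(object) {
  if (object@event) {
    if (object@peakTime < object@crossingTime - object@window / 2 - 1e-9 ||
        object@peakTime > object@crossingTime + object@window / 2 + 1e-9)
      return("peakTime outside the search window")
  }
  TRUE
})
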
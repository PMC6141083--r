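## Coarse-grained two-block model for constant-velocity pulling.
##
## A serpentine body of two 3x3 bead layers carries a hydrophobic core on
## its top face; a four-bead "C-terminal helix" docks over the core and
## shields it from solvent.  Pulling the chain terminus first undocks the
## helix (native helix-body contacts break, the core SASA jumps) and the
## spring force drops: the analog of the unfolding event whose force peak
## the rupture detector reports.  Oxidation makes the sulfoxide-bearing
## interface more hydrophilic, which the model expresses by scaling the
## well depth of the oxidizable helix-docking contacts.

#' Default toy-model specification
#'
#' @return list of the geometry and energy parameters accepted by
#'   [buildToyModel()]: bead spacing and radius, bond stiffness, contact
#'   well depths, oxidation factor, bead mass, jitter amplitude.
#' @export
toyModelSpec <- function() {
  list(
    spacing = 3.8,          # A between bonded beads
    helixGap = 3.4,         # A between helix beads and the core below
    beadRadius = 2.2,       # A
    bondK = 100,            # kcal/mol/A^2 (stiff chain: the body barely
                            # stretches before the helix releases)
    bodyContactEps = 20,    # kcal/mol, body-body native contacts (rigid fold)
    helixContactEps = 1.5,  # kcal/mol, helix-core docking contacts
    contactCut = 5.6,       # A, body pairs closer than this get a contact
    oxidationFactor = 1.0,  # scales oxidizable contact eps (< 1 = oxidized)
    mass = 100,             # amu per bead
    jitter = 0.05)          # A, seeded Gaussian jitter on built positions
}

#' Build the two-block pulling model
#'
#' Deterministic for a fixed seed (the seed only jitters bead positions by
#' `spec$jitter` A).  The oxidized variant of a model differs only in the
#' well depth of its oxidizable contacts: `oxidationFactor = 1` reproduces
#' the unoxidized model bit for bit, `oxidationFactor = 0.5` exactly
#' halves the docking contact eps.
#'
#' @param spec parameter list, see [toyModelSpec()]; entries override the
#'   defaults.
#' @param seed integer seed for the position jitter.
#' @return a [ToyModel-class] with 22 beads (18 body, 4 helix), the core
#'   set marked, and helix-docking contacts flagged oxidizable.
#' @export
buildToyModel <- function(spec = list(), seed = 1L) {
  p <- utils::modifyList(toyModelSpec(), spec)
  s <- p$spacing
  ## body: two 3x3 layers, serpentine chain (z = 0 then z = s)
  grid <- function(z) {
    xy <- rbind(c(0, 0), c(1, 0), c(2, 0), c(2, 1), c(1, 1), c(0, 1),
                c(0, 2), c(1, 2), c(2, 2))
    cbind(xy * s, z)
  }
  bottom <- grid(0)
  top <- grid(s)[9:1, , drop = FALSE]   # reverse so the chain climbs at (2,2)
  ## helix: four beads above the top layer's middle row (y = s), plus the
  ## pulled tail sticking out
  hz <- s + p$helixGap
  ## the free tail bead points up and away so it never occludes the core
  helix <- rbind(c(0, s, hz), c(s, s, hz), c(2 * s, s, hz),
                 c(3 * s + 2, s, hz + 2))
  pos <- rbind(bottom, top, helix)
  n <- nrow(pos)
  types <- c(rep("body", 18), rep("helix", 4))

  jitter <- withLocalSeed(seed, matrix(rnorm(3 * n, 0, p$jitter), n, 3))
  pos <- pos + jitter

  dist <- as.matrix(stats::dist(pos))
  bonds <- data.frame(i = seq_len(n - 1), j = seq_len(n - 1) + 1L)
  bonds$k <- p$bondK
  bonds$r0 <- dist[cbind(bonds$i, bonds$j)]

  bonded <- paste(bonds$i, bonds$j)
  contacts <- NULL
  ## body-body native contacts: everything within the cutoff, strong
  for (i in 1:17) for (j in (i + 1):18) {
    if (paste(i, j) %in% bonded) next
    if (dist[i, j] < p$contactCut)
      contacts <- rbind(contacts, data.frame(
        i = i, j = j, eps = p$bodyContactEps, r0 = dist[i, j],
        oxidizable = FALSE))
  }
  ## helix-docking contacts: every helix-body pair within the cutoff (the
  ## oxidizable, sulfoxide-sensitive interface; the lateral members keep
  ## the docked helix from sliding off thermally)
  for (h in 19:21) for (b in 1:18) {
    if (dist[h, b] < p$contactCut)
      contacts <- rbind(contacts, data.frame(
        i = b, j = h, eps = p$helixContactEps * p$oxidationFactor,
        r0 = dist[b, h], oxidizable = TRUE))
  }
  ## core: the top-layer middle-row beads shielded by the helix
  core <- which(abs(pos[, 2] - s) < s / 2 & abs(pos[, 3] - s) < s / 2 &
                types == "body")
  core <- intersect(core, 10:18)
  m <- new("ToyModel", positions = pos, types = types, bonds = bonds,
           contacts = contacts,
           coreSet = atomSet(core, n, "hydrophobic core"),
           beadRadius = p$beadRadius, mass = p$mass,
           oxidationFactor = p$oxidationFactor)
  validObject(m)
  m
}

#' Bead model as a Structure
#'
#' Renders a [ToyModel-class] (or one recorded frame of positions) as a
#' [Structure-class] of beads so the SASA/selection machinery applies.
#'
#' @param model a [ToyModel-class].
#' @param positions optional n x 3 matrix overriding the model positions.
#' @return a [Structure-class] with per-bead radii set.
#' @export
toyModelStructure <- function(model, positions = NULL) {
  pos <- if (is.null(positions)) model@positions else positions
  n <- nrow(pos)
  newStructure(serial = seq_len(n), name = "BD", element = "C",
               resname = "BEA", resid = seq_len(n), chain = "A",
               x = pos[, 1], y = pos[, 2], z = pos[, 3],
               radius = model@beadRadius, charge = 0,
               ljEpsilon = 0.1, ljRminHalf = model@beadRadius,
               provenance = "toy pulling model")
}
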
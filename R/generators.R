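## Seeded generators for every input the pipeline consumes, each carrying
## a ground-truth sidecar so downstream operations can be scored without
## re-deriving the truth.  Every generator is a pure function of
## (spec, seed).

groundTruth <- function(generator, seed, ...) {
  list(generator = generator, seed = seed, truth = list(...))
}

#' Write a ground-truth sidecar as JSON
#'
#' @param gt ground-truth list from a generator.
#' @param path JSON file.
#' @return `path`, invisibly.
#' @export
writeGroundTruth <- function(gt, path) {
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Crooks-consistent Gaussian work samples
#'
#' Forward work ~ Normal(dG + sigma^2/2, sigma^2) and backward work ~
#' Normal(-dG + sigma^2/2, sigma^2), in kT units: this Gaussian pair
#' satisfies the Crooks relation P_F(W) / P_R(-W) = exp(W - dG) exactly
#' (the density ratio is algebraic), so the generated WorkData has a known
#' true free-energy difference for scoring the estimators.  Samples are
#' exported in kcal/mol at the stated temperature.
#'
#' @param trueDg true delta-G, kT units.
#' @param sigma work spread, kT units (>= 0; 0 gives delta distributions).
#' @param nForward,nBackward samples per direction.
#' @param seed integer seed.
#' @param temperature K used for the unit conversion on export.
#' @return list with `work` (a single-transition [WorkData-class]) and
#'   `groundTruth` (true dG in kT and kcal/mol).
#' @export
genCrooksSamples <- function(trueDg, sigma, nForward = 5000L,
                             nBackward = 5000L, seed = 1L,
                             temperature = 300) {
  stopifnot(sigma >= 0)
  kt <- kT(temperature)
  samp <- withLocalSeed(seed, list(
    f = rnorm(nForward, trueDg + sigma^2 / 2, sigma),
    b = rnorm(nBackward, -trueDg + sigma^2 / 2, sigma)))
  work <- new("WorkData", forward = list(samp$f * kt),
              backward = list(samp$b * kt), lambdas = c(0, 1),
              temperature = temperature)
  list(work = work,
       groundTruth = groundTruth("crooks", seed, true_dg_kbt = trueDg,
                                 true_dg_kcalmol = trueDg * kt,
                                 sigma_kbt = sigma))
}

## Free-sphere SASA of one bead.
freeSphereSasa <- function(radius, probe = 1.4) 4 * pi * (radius + probe)^2

#' Toy structure with sites of prescribed burial
#'
#' Builds one bead cluster per requested site, 60 A apart: an "exposed"
#' site is a bare bead, a "buried" site sits inside a closed shell of
#' neighbor beads, and a "partial" site carries a hemispherical shell.
#' The emulated contrast is a solvent-exposed methionine side chain
#' versus ones packed inside the fold.
#'
#' @param sites named character vector mapping site labels to burial
#'   classes (`"exposed"`, `"partial"`, `"buried"`).
#' @param seed integer seed (orients the shells).
#' @param siteRadius bead radius of the site atom, A.
#' @param shellDistance neighbor-shell distance for buried sites, A.
#' @param partialDistance hemisphere distance for partial sites, A (the
#'   looser shell leaves the site about half exposed).
#' @return list with `structure` (a [Structure-class]; site beads are
#'   residue `SIT`, neighbors `NBR`, one residue id per site in input
#'   order) and `groundTruth` (class and free-sphere fraction bounds per
#'   site).
#' @export
genToyStructure <- function(sites, seed = 1L, siteRadius = 1.9,
                            shellDistance = 3.0, partialDistance = 6.0) {
  classes <- vapply(as.character(sites), function(s)
    match.arg(s, c("exposed", "partial", "buried")), character(1))
  nShell <- 30L
  rows <- list()
  serial <- 0L
  withLocalSeed(seed, {
    for (k in seq_along(classes)) {
      centre <- c(60 * (k - 1), 0, 0)
      serial <- serial + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        serial = serial, name = "ST", resname = "SIT", resid = k,
        x = centre[1], y = centre[2], z = centre[3])
      if (classes[k] != "exposed") {
        dirs <- spherePoints(nShell)
        ## random shell orientation so generated structures differ by seed
        th <- runif(1, 0, 2 * pi)
        rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                      3, 3, byrow = TRUE)
        dirs <- dirs %*% rot
        d <- shellDistance
        if (classes[k] == "partial") {
          dirs <- dirs[dirs[, 3] < 0, ]
          d <- partialDistance
        }
        for (m in seq_len(nrow(dirs))) {
          serial <- serial + 1L
          p <- centre + dirs[m, ] * d
          rows[[length(rows) + 1L]] <- data.frame(
            serial = serial, name = sprintf("N%d", m), resname = "NBR",
            resid = 1000L + serial, x = p[1], y = p[2], z = p[3])
        }
      }
    }
  })
  d <- do.call(rbind, rows)
  st <- newStructure(serial = d$serial, name = d$name, element = "C",
                     resname = d$resname, resid = d$resid, chain = "A",
                     x = d$x, y = d$y, z = d$z, radius = siteRadius,
                     charge = 0, ljEpsilon = 0.1, ljRminHalf = siteRadius,
                     provenance = "toy burial fixture")
  truth <- groundTruth("toy_structure", seed,
                       classes = as.list(setNames(classes, names(sites))),
                       free_sphere_A2 = freeSphereSasa(siteRadius))
  list(structure = st, groundTruth = truth)
}

#' Ala-Met-Ala tripeptide stand-in for the unfolded state
#'
#' Deterministic extended-conformation heavy-atom model whose central
#' methionine side chain points away from the backbone and is essentially
#' fully solvent exposed — the unfolded-state proxy for the thermodynamic
#' cycle.  The sulfoxide builder applies cleanly to its central residue.
#'
#' @return a [Structure-class] (18 heavy atoms: 4 backbone + CB per
#'   alanine, 4 backbone + CB, CG, SD, CE for the methionine).
#' @export
genTripeptide <- function() {
  ## idealized extended backbone along x, side chains along +z
  res <- function(resid, resname, x0, side) {
    b <- data.frame(
      name = c("N", "CA", "C", "O"),
      x = x0 + c(0, 1.46, 2.9, 3.0),
      y = c(0.4, 0, 0.45, 1.1),
      z = 0)
    s <- NULL
    if (identical(side, "ALA")) {
      s <- data.frame(name = "CB", x = x0 + 1.46, y = -0.6, z = 1.4)
    } else if (identical(side, "MET")) {
      ## coarse side-chain placement: the bead column stands 5.5 A off
      ## the backbone and marches away in 2.2 A steps, so the group
      ## keeps > 90% of its free surface (covalent geometry would put
      ## CB against CA and forfeit ~1/3 of it)
      s <- data.frame(
        name = c("CB", "CG", "SD", "CE"),
        x = x0 + c(1.46, 1.46, 1.46, 1.46),
        y = -2.31 - 1.232 * (0:3),
        z = 5.28 + 1.826 * (0:3))
    }
    d <- rbind(b, s)
    d$resname <- resname
    d$resid <- resid
    d
  }
  d <- rbind(res(1, "ALA", 0, "ALA"), res(2, "MET", 3.8, "MET"),
             res(3, "ALA", 7.6, "ALA"))
  newStructure(serial = seq_len(nrow(d)), name = d$name,
               element = substr(d$name, 1, 1), resname = d$resname,
               resid = d$resid, chain = "A", x = d$x, y = d$y, z = d$z,
               provenance = "Ala-Met-Ala extended model")
}

#' Synthetic pulling fixture with known rupture
#'
#' Force = baseline + triangular peak (+ Gaussian noise); core SASA = a
#' logistic step with 40 ps width crossing the 50 A^2 threshold at the
#' specified record (the step width guarantees the detector's two-record
#' persistence rule is exercised, not fought).  Ground truth records the
#' exact crossing time, peak time and peak force.
#'
#' @param peakSpec list: `crossingTime` ps, `peakOffset` ps (peak time -
#'   crossing time), `peakForce` pN, `baselineForce` pN, `span` ps,
#'   `dt` ps, `peakHalfWidth` ps, `lowSasa`/`highSasa` A^2.  Sensible
#'   defaults are filled for missing entries.
#' @param noiseSd force noise SD, pN.
#' @param seed integer seed.
#' @return list with `force` and `sasa` ([Series-class]) and
#'   `groundTruth`.
#' @export
genPullingFixture <- function(peakSpec = list(), noiseSd = 0, seed = 1L) {
  p <- utils::modifyList(list(
    crossingTime = 5000, peakOffset = 120, peakForce = 900,
    baselineForce = 100, span = 10000, dt = 10, peakHalfWidth = 30,
    lowSasa = 20, highSasa = 80), peakSpec)
  times <- seq(0, p$span, by = p$dt)
  peakTime <- p$crossingTime + p$peakOffset
  if (peakTime > p$span || peakTime < 0)
    oxStop("peak offset places the peak outside the series span",
           "oxfold_spec_error")
  tri <- pmax(0, 1 - abs(times - peakTime) / p$peakHalfWidth)
  force <- p$baselineForce + (p$peakForce - p$baselineForce) * tri
  force <- force + withLocalSeed(seed, rnorm(length(times), 0, noiseSd))
  ## logistic step of ~40 ps width; midpoint half a record before the
  ## nominal crossing so the crossing sample is the first one above 50
  sasa <- p$lowSasa + (p$highSasa - p$lowSasa) /
    (1 + exp(-(times - (p$crossingTime - p$dt / 2)) / 10))
  crossing <- if (any(sasa > 50)) times[which(sasa > 50)[1]] else NA
  list(force = newSeries(times, force, "force_pN"),
       sasa = newSeries(times, sasa, "sasa_A2"),
       groundTruth = groundTruth(
         "pulling_fixture", seed, crossing_time_ps = crossing,
         peak_time_ps = if (is.na(crossing)) NA else peakTime,
         peak_force_pN = if (is.na(crossing)) NA else p$peakForce,
         noise_sd_pN = noiseSd))
}

#' Hydrogen-bond geometry frames with known counts
#'
#' Each frame poses water-like probes (O + 2 H) around a fixed acceptor
#' oxygen at exact H...acceptor distances and donor-H...acceptor angles.
#' Ground truth records how many probes qualify per frame under the
#' 2.7 A / 120 degree criteria (inclusive boundaries).
#'
#' @param geometryList list of frames; each frame is a list of
#'   `c(distance, angle)` pairs (A, degrees), one per water probe.
#' @param frameInterval ps.
#' @return list with `trajectory` ([Trajectory-class]; acceptor residue
#'   `ACC` resid 1, waters `HOH`), `donors`/`acceptors` index vectors,
#'   and `groundTruth` (qualifying count per frame).
#' @export
genHbondFrames <- function(geometryList, frameInterval = 10) {
  nWater <- max(vapply(geometryList, length, integer(1)))
  if (nWater == 0)
    oxStop("need at least one water geometry", "oxfold_spec_error")
  buildFrame <- function(geoms, modelId) {
    rows <- data.frame(serial = 1L, name = "O", element = "O",
                       resname = "ACC", resid = 1L)
    xyz <- matrix(c(0, 0, 0), 1, 3)
    for (w in seq_len(nWater)) {
      ## park unused probes far away so every frame shares one topology
      if (w <= length(geoms)) {
        dist <- geoms[[w]][1]; ang <- geoms[[w]][2] * pi / 180
        if (dist <= 0) oxStop("infeasible geometry", "oxfold_spec_error")
      } else {
        dist <- 50 + 10 * w; ang <- pi
      }
      ## spread successive probes around the acceptor (rotation about z
      ## preserves every distance and angle to the acceptor at the origin)
      phi <- 2 * pi * (w - 1) / max(1, nWater)
      rot <- matrix(c(cos(phi), -sin(phi), 0,
                      sin(phi), cos(phi), 0,
                      0, 0, 1), 3, 3, byrow = TRUE)
      h1 <- c(dist, 0, 0)
      ## donor O at 0.96 A from H, at the requested angle from H -> acceptor
      hd <- c(cos(ang) * -1, sin(ang), 0)
      o <- h1 + 0.96 * hd
      ## second hydrogen completes the water out of plane (104.5 degree
      ## H-O-H angle), so it can never qualify itself
      u <- (h1 - o) / 0.96
      v <- cos(1.823) * u + sin(1.823) * c(0, 0, 1)
      h2 <- o + 0.96 * v
      pts <- rbind(o, h1, h2) %*% t(rot)
      base <- nrow(rows)
      rows <- rbind(rows, data.frame(
        serial = base + 1:3, name = c("O", "H1", "H2"),
        element = c("O", "H", "H"), resname = "HOH",
        resid = w + 1L))
      xyz <- rbind(xyz, pts)
    }
    newStructure(serial = rows$serial, name = rows$name,
                 element = rows$element, resname = rows$resname,
                 resid = rows$resid, chain = "A", x = xyz[, 1],
                 y = xyz[, 2], z = xyz[, 3], modelId = modelId,
                 provenance = "hbond geometry fixture")
  }
  frames <- lapply(seq_along(geometryList), function(k)
    buildFrame(geometryList[[k]], k))
  counts <- vapply(geometryList, function(geoms)
    sum(vapply(geoms, function(g)
      g[1] <= 2.7 + 1e-9 && g[2] >= 120 - 1e-9, logical(1))), integer(1))
  list(trajectory = new("Trajectory", frames = frames,
                        frameInterval = frameInterval),
       donorResids = seq_len(nWater) + 1L,
       groundTruth = groundTruth("hbond_frames", 0L,
                                 bonds_per_frame = as.list(counts)))
}
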
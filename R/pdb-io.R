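## PDB reading and writing.  Parsing and formatting of the fixed-column
## records is delegated to bio3d; a light pre-scan of the raw lines supplies
## line-numbered parse errors and per-MODEL topology checks up front.

#' Construct a Structure from atom fields
#'
#' Low-level constructor used by the readers and generators.  Parameter
#' fields default to `NA` until assigned.
#'
#' @param serial,name,element,resname,resid,chain,x,y,z atom fields.
#' @param radius,charge,ljEpsilon,ljRminHalf optional per-atom parameters.
#' @param modelId integer model number.
#' @param provenance free-text origin.
#' @return a [Structure-class].
#' @export
newStructure <- function(serial, name, element, resname, resid, chain,
                         x, y, z, radius = NA_real_, charge = NA_real_,
                         ljEpsilon = NA_real_, ljRminHalf = NA_real_,
                         modelId = 1L, provenance = "") {
  n <- length(serial)
  atoms <- data.frame(
    serial = as.integer(serial), name = as.character(name),
    element = as.character(element), resname = as.character(resname),
    resid = as.integer(resid), chain = as.character(chain),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    radius = rep_len(as.numeric(radius), n),
    charge = rep_len(as.numeric(charge), n),
    ljEpsilon = rep_len(as.numeric(ljEpsilon), n),
    ljRminHalf = rep_len(as.numeric(ljRminHalf), n),
    stringsAsFactors = FALSE)
  new("Structure", atoms = atoms, modelId = as.integer(modelId),
      provenance = provenance)
}

## Guess an element symbol from a PDB atom name when columns 77-78 are blank.
guessElement <- function(name) {
  nm <- gsub("[0-9' ]", "", name)
  two <- toupper(substr(nm, 1, 2))
  ifelse(two %in% c("CL", "NA", "MG", "FE", "ZN", "BR"),
         two, substr(nm, 1, 1))
}

## Pre-scan raw PDB lines: malformed ATOM/HETATM records raise a
## line-numbered parse error; MODEL blocks with unequal atom counts raise a
## topology error.  Returns the per-model atom counts.
scanPDBLines <- function(lines) {
  modelCounts <- integer(0)
  current <- 0L
  inModel <- FALSE
  sawModel <- FALSE
  for (i in seq_along(lines)) {
    ln <- lines[i]
    rec <- substr(ln, 1, 6)
    if (startsWith(rec, "MODEL")) {
      if (inModel) modelCounts <- c(modelCounts, current)
      inModel <- TRUE; sawModel <- TRUE; current <- 0L
    } else if (startsWith(rec, "ENDMDL")) {
      modelCounts <- c(modelCounts, current)
      inModel <- FALSE; current <- 0L
    } else if (rec %in% c("ATOM  ", "HETATM")) {
      if (nchar(ln) < 54)
        oxStop(sprintf("malformed PDB record at line %d: too short", i),
               "oxfold_parse_error")
      nums <- suppressWarnings(c(
        as.numeric(substr(ln, 31, 38)), as.numeric(substr(ln, 39, 46)),
        as.numeric(substr(ln, 47, 54))))
      ser <- suppressWarnings(as.integer(substr(ln, 7, 11)))
      if (any(is.na(nums)) || is.na(ser))
        oxStop(sprintf(
          "malformed PDB record at line %d: unparseable numeric field", i),
          "oxfold_parse_error")
      current <- current + 1L
    }
  }
  if (inModel) modelCounts <- c(modelCounts, current)
  if (!sawModel) modelCounts <- current
  if (length(unique(modelCounts[modelCounts > 0])) > 1)
    oxStop(paste("MODEL blocks have inconsistent atom counts:",
                 paste(modelCounts, collapse = ", ")),
           "oxfold_topology_error")
  modelCounts
}

#' Read a PDB file
#'
#' Reads ATOM/HETATM records (via \pkg{bio3d}) into a [Structure-class], or,
#' with `multiModel = TRUE`, every MODEL block into a [Trajectory-class]
#' whose frames share one topology.  Coordinates are Angstrom; atom order,
#' serials and residue ids are preserved as read.
#'
#' @param path PDB file.
#' @param multiModel read all MODEL blocks as trajectory frames.
#' @param frameInterval ps between frames (trajectories only; PDB itself
#'   carries no time base).
#' @return a [Structure-class], or a [Trajectory-class] when
#'   `multiModel = TRUE`.
#' @examples
#' pdb <- system.file("extdata", "met_fixture.pdb", package = "oxfold")
#' readPDB(pdb)
#' @export
readPDB <- function(path, multiModel = FALSE, frameInterval = 10) {
  if (!file.exists(path))
    oxStop(paste("file not found:", path), "oxfold_io_error")
  lines <- readLines(path, warn = FALSE)
  scanPDBLines(lines)
  pdb <- bio3d::read.pdb(path, multi = multiModel, verbose = FALSE)
  at <- pdb$atom
  elem <- at$elesy
  blank <- is.na(elem) | !nzchar(trimws(elem))
  elem[blank] <- guessElement(at$elety[blank])
  chain <- at$chain
  chain[is.na(chain)] <- "A"
  build <- function(xyz, modelId) {
    newStructure(serial = at$eleno, name = at$elety, element = trimws(elem),
                 resname = at$resid, resid = at$resno, chain = chain,
                 x = xyz[1, ], y = xyz[2, ], z = xyz[3, ],
                 modelId = modelId, provenance = basename(path))
  }
  if (!multiModel) {
    xyz <- matrix(pdb$xyz[1, ], nrow = 3)
    return(build(xyz, 1L))
  }
  nm <- nrow(pdb$xyz)
  frames <- lapply(seq_len(nm), function(m)
    build(matrix(pdb$xyz[m, ], nrow = 3), m))
  new("Trajectory", frames = frames, frameInterval = frameInterval)
}

#' Write a structure or trajectory as PDB
#'
#' Round trips with [readPDB()]: atom names, residue bookkeeping and
#' coordinates survive to the format's 3-decimal precision.  Trajectories
#' are written as one MODEL/ENDMDL block per frame.
#'
#' @param x a [Structure-class] or [Trajectory-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePDB <- function(x, path) {
  if (is(x, "Trajectory")) {
    topo <- x@frames[[1]]
    xyz <- do.call(rbind, lapply(x@frames, function(f)
      as.vector(t(coords(f)))))
  } else if (is(x, "Structure")) {
    topo <- x
    xyz <- matrix(as.vector(t(coords(x))), nrow = 1)
  } else {
    oxStop("x must be a Structure or Trajectory", "oxfold_type_error")
  }
  a <- topo@atoms
  if (!all(is.finite(xyz)))
    oxStop("cannot write non-finite coordinates", "oxfold_format_error")
  if (any(a$serial > 99999L) || any(abs(xyz) >= 1e4))
    oxStop("field width exceeded (serial > 99999 or |coord| >= 10^4 A)",
           "oxfold_format_error")
  bio3d::write.pdb(pdb = NULL, file = path, xyz = xyz, resno = a$resid,
                   resid = a$resname, eleno = a$serial, elety = a$name,
                   chain = a$chain, elesy = a$element)
  invisible(path)
}
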
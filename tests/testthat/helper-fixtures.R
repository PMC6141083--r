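# Shared fixtures, built in code at test time.

# Four-atom toy PDB written to a temp file; returns the path.
write4AtomPDB <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(c(
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   GLY A   1       2.009   1.420   0.123  1.00  0.00           C",
    "ATOM      4  O   GLY A   1       1.251   2.390   0.123  1.00  0.00           O",
    "END"), path)
  path
}

metFixturePath <- function() {
  system.file("extdata", "met_fixture.pdb", package = "oxfold")
}

# A bare structure of point atoms at given coordinates with a common radius.
pointStructure <- function(xyz, radius = 1.9, resname = "SIT") {
  xyz <- matrix(xyz, ncol = 3)
  newStructure(serial = seq_len(nrow(xyz)), name = "ST", element = "C",
               resname = resname, resid = seq_len(nrow(xyz)), chain = "A",
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], radius = radius,
               charge = 0, ljEpsilon = 0.1, ljRminHalf = radius)
}

# Monte-Carlo SASA oracle: uniform random points on each expanded sphere,
# rejection against all other expanded spheres.
sasaMonteCarlo <- function(structure, probe = 1.4, nPoints = 1e5) {
  a <- atoms(structure)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  R <- a$radius + probe
  total <- 0
  for (i in seq_len(nrow(a))) {
    z <- runif(nPoints, -1, 1)
    phi <- runif(nPoints, 0, 2 * pi)
    r <- sqrt(1 - z^2)
    p <- cbind(r * cos(phi), r * sin(phi), z) * R[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    keep <- rep(TRUE, nPoints)
    for (j in seq_len(nrow(a))[-i]) {
      d2 <- rowSums(sweep(p, 2, xyz[j, ])^2)
      keep <- keep & d2 >= R[j]^2
    }
    total <- total + 4 * pi * R[i]^2 * mean(keep)
  }
  total
}

# A water molecule posed so its O-H points at an acceptor at the origin
# with the requested H...acceptor distance and donor-H...acceptor angle.
waterAt <- function(distance, angleDeg) {
  ang <- angleDeg * pi / 180
  h1 <- c(distance, 0, 0)
  o <- h1 + 0.96 * c(-cos(ang), sin(ang), 0)
  u <- (h1 - o) / 0.96
  h2 <- o + 0.96 * (cos(1.823) * u + sin(1.823) * c(0, 0, 1))
  rbind(o, h1, h2)
}

# Acceptor O + one water, as a parameterized structure.
acceptorWaterStructure <- function(distance, angleDeg) {
  w <- waterAt(distance, angleDeg)
  newStructure(serial = 1:4, name = c("O", "O", "H1", "H2"),
               element = c("O", "O", "H", "H"),
               resname = c("ACC", "HOH", "HOH", "HOH"),
               resid = c(1L, 2L, 2L, 2L), chain = "A",
               x = c(0, w[, 1]), y = c(0, w[, 2]), z = c(0, w[, 3]),
               radius = 1.5)
}
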
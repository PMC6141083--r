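# Structure model: PDB I/O, selection grammar, parameter assignment,
# sulfoxide building.

test_that("PDB round trip preserves topology and coordinates to 3 decimals", {
  p <- write4AtomPDB()
  s <- readPDB(p)
  expect_s4_class(s, "Structure")
  expect_equal(nAtoms(s), 4L)
  expect_equal(atoms(s)$name, c("N", "CA", "C", "O"))
  expect_equal(coords(s)[2, ], c(1.458, 0, 0), ignore_attr = TRUE)
  out <- tempfile(fileext = ".pdb")
  writePDB(s, out)
  s2 <- readPDB(out)
  expect_equal(atoms(s2)$name, atoms(s)$name)
  expect_equal(atoms(s2)$resname, atoms(s)$resname)
  expect_equal(atoms(s2)$resid, atoms(s)$resid)
  expect_equal(coords(s2), coords(s), tolerance = 1e-9)
  # coordinate columns byte-identical on rewrite
  out2 <- tempfile(fileext = ".pdb")
  writePDB(s2, out2)
  c1 <- substr(grep("^ATOM", readLines(out), value = TRUE), 31, 54)
  c2 <- substr(grep("^ATOM", readLines(out2), value = TRUE), 31, 54)
  expect_identical(c1, c2)

  # the packaged methionine fixture round trips too
  sm <- readPDB(metFixturePath())
  outm <- tempfile(fileext = ".pdb")
  writePDB(sm, outm)
  expect_equal(coords(readPDB(outm)), coords(sm), tolerance = 1e-9)
})

test_that("multi-model files become trajectories; unequal models error", {
  p <- write4AtomPDB()
  base <- readLines(p)
  atomLines <- base[1:4]
  tf <- tempfile(fileext = ".pdb")
  writeLines(c("MODEL        1", atomLines, "ENDMDL",
               "MODEL        2", sub("0\\.000", "1.000", atomLines), "ENDMDL",
               "MODEL        3", atomLines, "ENDMDL", "END"), tf)
  tr <- readPDB(tf, multiModel = TRUE, frameInterval = 10)
  expect_s4_class(tr, "Trajectory")
  expect_equal(nFrames(tr), 3L)
  expect_equal(frameInterval(tr), 10)

  # trajectory writing emits one MODEL block per frame and round trips
  out <- tempfile(fileext = ".pdb")
  writePDB(tr, out)
  expect_equal(sum(grepl("^MODEL", readLines(out))), 3L)
  tr2 <- readPDB(out, multiModel = TRUE)
  expect_equal(coords(frames(tr2)[[2]]), coords(frames(tr)[[2]]),
               tolerance = 1e-9)

  bad <- tempfile(fileext = ".pdb")
  writeLines(c("MODEL        1", atomLines, "ENDMDL",
               "MODEL        2", atomLines[1:3], "ENDMDL", "END"), bad)
  expect_error(readPDB(bad, multiModel = TRUE),
               class = "oxfold_topology_error")
})

test_that("malformed records and unwritable fields raise classed errors", {
  p <- write4AtomPDB()
  lines <- readLines(p)
  lines[2] <- paste0(substr(lines[2], 1, 30), "  xx.xxx",
                     substr(lines[2], 39, nchar(lines[2])))
  bad <- tempfile(fileext = ".pdb")
  writeLines(lines, bad)
  err <- expect_error(readPDB(bad), class = "oxfold_parse_error")
  expect_match(conditionMessage(err), "line 2")

  s <- readPDB(p)
  s@atoms$x[1] <- NaN
  expect_error(writePDB(s, tempfile()), class = "oxfold_format_error")
  s2 <- readPDB(p)
  s2@atoms$serial[1] <- 123456L
  expect_error(writePDB(s2, tempfile()), class = "oxfold_format_error")
})

test_that("selection grammar covers the documented constructs", {
  s <- readPDB(metFixturePath())
  side <- selectAtoms(s, "resid 1606 and sidechain")
  expect_setequal(atoms(s)$name[indices(side)], c("CB", "CG", "SD", "CE"))
  rest <- selectAtoms(s, "protein and not resid 1606")
  expect_setequal(atoms(s)$resid[indices(rest)], 1607)
  # complement within the protein universe
  prot <- selectAtoms(s, "protein")
  expect_setequal(
    c(indices(selectAtoms(s, "protein and resid 1606")), indices(rest)),
    indices(prot))
  expect_error(selectAtoms(s, "resid 9999"),
               class = "oxfold_empty_selection")
  expect_error(selectAtoms(s, "residue 1606"), class = "oxfold_grammar_error")
})

test_that("selection is idempotent and respects De Morgan identities", {
  s <- readPDB(metFixturePath())
  specs <- c("sidechain", "resid 1606", "name CA CB", "backbone or resname ALA")
  for (sp in specs) {
    expect_identical(indices(selectAtoms(s, sp)), indices(selectAtoms(s, sp)))
  }
  # not (A or B) == (not A) and (not B); not (A and B) == (not A) or (not B)
  a <- "resid 1606"; b <- "name CA C O"
  expect_identical(
    indices(selectAtoms(s, sprintf("not (%s or %s)", a, b))),
    indices(selectAtoms(s, sprintf("(not %s) and (not %s)", a, b))))
  expect_identical(
    indices(selectAtoms(s, sprintf("not (%s and %s)", a, b))),
    indices(selectAtoms(s, sprintf("(not %s) or (not %s)", a, b))))
  # complement partitions the universe
  sel <- selectAtoms(s, "sidechain")
  expect_setequal(c(indices(sel), indices(complementSet(sel))),
                  seq_len(nAtoms(s)))
})

test_that("parameter assignment resolves every atom or reports offenders", {
  s <- readPDB(metFixturePath())
  sp <- assignParams(s)
  a <- atoms(sp)
  expect_true(all(a$radius > 0))
  expect_equal(a$radius[a$name == "SD"], 1.80)
  # the table is constructed neutral per residue
  expect_equal(sum(a$charge[a$resid == 1606]), 0, tolerance = 1e-6)
  expect_equal(sum(a$charge[a$resid == 1607]), 0, tolerance = 1e-6)

  s@atoms$name[5] <- "XX"
  s@atoms$element[5] <- "Xx"
  err <- expect_error(assignParams(s),
                      class = "oxfold_parameterization_error")
  expect_match(conditionMessage(err), "XX")
})

test_that("sulfoxide building adds exactly one oxygen at the S=O length", {
  s <- assignParams(readPDB(metFixturePath()))
  r <- buildSulfoxide(s, 1606, details = TRUE)
  s2 <- r$structure
  expect_equal(nAtoms(s2), nAtoms(s) + 1L)
  a <- atoms(s2)
  expect_equal(sum(a$name == "OD"), 1L)
  expect_setequal(unique(a$resname[a$resid == 1606]), "MSX")
  od <- unlist(a[a$name == "OD", c("x", "y", "z")])
  sd_ <- unlist(a[a$name == "SD", c("x", "y", "z")])
  expect_equal(sqrt(sum((od - sd_)^2)), 1.50, tolerance = 1e-9)
  # unobstructed placement keeps the default angle with zero overlap
  expect_equal(r$score, 0)
  # environment untouched
  expect_equal(a[a$resid == 1607, c("x", "y", "z")],
               atoms(s)[atoms(s)$resid == 1607, c("x", "y", "z")],
               ignore_attr = TRUE)
})

test_that("an obstruction on the default bisector forces a rotation", {
  s <- assignParams(readPDB(metFixturePath()))
  base <- buildSulfoxide(s, 1606, details = TRUE)
  odPos <- unlist(atoms(base$structure)[atoms(base$structure)$name == "OD",
                                        c("x", "y", "z")])
  # park a foreign atom exactly on the default oxygen position
  blocker <- atoms(s)[1, ]
  blocker$serial <- 999L
  blocker$name <- "BL"
  blocker$resname <- "BLK"
  blocker$resid <- 2000L
  blocker$x <- odPos[1]; blocker$y <- odPos[2]; blocker$z <- odPos[3]
  s@atoms <- rbind(s@atoms, blocker)
  validObject(s)
  r <- buildSulfoxide(s, 1606, details = TRUE)
  expect_gt(r$scores[1], r$score)   # rotated angle strictly beats default
  expect_false(r$angle == 0)
})

test_that("sulfoxide errors: wrong residue type, incomplete side chain", {
  s <- readPDB(metFixturePath())
  expect_error(buildSulfoxide(s, 1607), class = "oxfold_type_error")
  s@atoms <- s@atoms[s@atoms$name != "CE", ]
  expect_error(buildSulfoxide(s, 1606),
               class = "oxfold_incomplete_residue")
})

test_that("each methionine of a multi-Met structure gains exactly one atom", {
  # five copies of the Met fixture residue strung along x
  one <- atoms(readPDB(metFixturePath()))
  one <- one[one$resid == 1606, ]
  all5 <- do.call(rbind, lapply(0:4, function(k) {
    r <- one
    r$x <- r$x + 12 * k
    r$resid <- 1600L + k
    r$serial <- r$serial + 100L * k
    r
  }))
  s <- newStructure(all5$serial, all5$name, all5$element, all5$resname,
                    all5$resid, all5$chain, all5$x, all5$y, all5$z)
  for (rid in 1600:1604) {
    s2 <- buildSulfoxide(s, rid)
    expect_equal(nAtoms(s2), nAtoms(s) + 1L)
    expect_equal(sum(atoms(s2)$resname == "MSX"), 9L)  # 8 + OD
  }
})
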
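# Coarse-grained pulling: spring force, model construction, integrator
# diagnostics, and the rupture phenomenology of the two-block model.

test_that("spring force follows Hook's law with the pN mirror", {
  expect_equal(springForce(5, 5, 2), c(kcalmolA = 0, pN = 0))
  f <- springForce(6, 5, 2)
  expect_equal(f[["kcalmolA"]], 2)
  expect_equal(f[["pN"]], 138.9572, tolerance = 1e-6)
  # linearity and 3-vector projection form
  expect_equal(springForce(7, 5, 2)[["kcalmolA"]],
               2 * springForce(6, 5, 2)[["kcalmolA"]])
  f3 <- springForce(c(3, 4, 0), c(1, 4, 0), 1.5, axis = c(1, 0, 0))
  expect_equal(f3[["kcalmolA"]], 3)
  # off-axis displacement does not load the spring
  f4 <- springForce(c(1, 9, 0), c(1, 4, 0), 1.5, axis = c(1, 0, 0))
  expect_equal(f4[["kcalmolA"]], 0)
})

test_that("the built model shields its core below the 50 A^2 threshold", {
  m <- buildToyModel(seed = 1)
  st <- toyModelStructure(m)
  built <- sasaFrame(st, m@coreSet, nPoints = 960)@groupTotal
  expect_lt(built, 50)
  # displacing the helix block exposes the core well past the threshold
  pos <- m@positions
  pos[m@types == "helix", 3] <- pos[m@types == "helix", 3] + 30
  undocked <- sasaFrame(toyModelStructure(m, pos), m@coreSet,
                        nPoints = 960)@groupTotal
  expect_gt(undocked, 50)
})

test_that("oxidation scales only the oxidizable contacts", {
  wt <- buildToyModel(seed = 3)
  ox <- buildToyModel(list(oxidationFactor = 0.5), seed = 3)
  expect_identical(wt@positions, ox@positions)
  expect_identical(wt@bonds, ox@bonds)
  oxi <- wt@contacts$oxidizable
  expect_equal(ox@contacts$eps[oxi], wt@contacts$eps[oxi] / 2)
  expect_identical(ox@contacts$eps[!oxi], wt@contacts$eps[!oxi])
  # factor 1 reproduces the unoxidized model bit for bit
  same <- buildToyModel(list(oxidationFactor = 1), seed = 3)
  expect_identical(same@contacts, wt@contacts)
})

test_that("a free dummy exerts no force while the bead diffuses", {
  m <- buildToyModel(seed = 2)
  r <- runCVPulling(m, pullParams(springK = 0, duration = 0.2),
                    seed = 4, coreSasa = FALSE)
  d <- traceData(r$trace)
  expect_true(all(d$force_kcalmolA == 0))
  expect_gt(sd(d$pulled_A), 0)   # thermal diffusion
})

test_that("a static dummy leaves the spring force drifting around zero", {
  m <- buildToyModel(seed = 2)
  r <- runCVPulling(m, pullParams(velocity = 0, duration = 1), seed = 5,
                    coreSasa = FALSE)
  f <- traceData(r$trace)$force_kcalmolA
  # equilibrium: the mean spring load stays far below the ~3.3 kcal/mol/A
  # rupture scale (thermal relaxation off the built geometry contributes
  # a small static offset)
  expect_lt(abs(mean(f)), 1)
  expect_lt(abs(mean(f)), 2 * sd(f))
})

test_that("runs are deterministic given (model, params, seed)", {
  m <- buildToyModel(seed = 1)
  d1 <- traceData(runCVPulling(m, pullParams(duration = 0.1), seed = 9,
                               coreSasa = FALSE)$trace)
  d2 <- traceData(runCVPulling(m, pullParams(duration = 0.1), seed = 9,
                               coreSasa = FALSE)$trace)
  expect_identical(d1, d2)
  # force = springK * extension at every record (trace invariant)
  expect_equal(d1$force_kcalmolA, 2 * d1$extension_A, tolerance = 1e-9)
})

test_that("the integrator conserves energy without friction or pulling", {
  m <- buildToyModel(seed = 1)
  r <- runCVPulling(m, pullParams(springK = 0, velocity = 0, friction = 0,
                                  dt = 2, duration = 0.2,
                                  recordInterval = 1),
                    seed = 1, coreSasa = FALSE)   # 1e5 steps at 2 fs
  d <- traceData(r$trace)
  etot <- d$kinetic_kcalmol + d$potential_kcalmol
  # drift under 1% of the thermal kinetic energy scale
  expect_lt(max(etot) - min(etot), 0.01 * abs(mean(etot)) +
              0.01 * mean(d$kinetic_kcalmol))
})

test_that("the thermostat equipartitions kinetic energy within 5%", {
  m <- buildToyModel(seed = 1)
  r <- runCVPulling(m, pullParams(springK = 0, velocity = 0, duration = 2),
                    seed = 5, coreSasa = FALSE)
  ke <- traceData(r$trace)$kinetic_kcalmol
  perBead <- mean(ke[-(1:20)]) / 21   # fixed bead carries none
  expect_equal(perBead, 1.5 * kT(300), tolerance = 0.05)
})

test_that("oversized time steps raise the instability error", {
  m <- buildToyModel(seed = 1)
  expect_error(
    runCVPulling(m, pullParams(dt = 500, duration = 0.5), seed = 1,
                 coreSasa = FALSE),
    class = "oxfold_instability_error")
})

test_that("pulling the default model produces a rupture with a force drop", {
  m <- buildToyModel(seed = 1)
  r <- runCVPulling(m, seed = 101)
  ev <- traceRupture(r$trace)
  expect_true(hasEvent(ev))
  # after the crossing the smoothed force drops by > 25% off its peak
  d <- traceData(r$trace)
  fm <- runningAverage(traceSeries(r$trace, "force_pN"), 20)@values
  t <- d$time_ps
  post <- fm[t >= ev@peakTime & t <= ev@peakTime + 300]
  expect_lt(min(post), 0.75 * peakForce(ev))
  # the trajectory mirror shares the record grid and writes as PDB
  expect_equal(nFrames(r$trajectory), nrow(d))
  out <- tempfile(fileext = ".pdb")
  writePDB(r$trajectory, out)
  expect_equal(sum(grepl("^MODEL", readLines(out))), nrow(d))
})

test_that("pulling traces round trip through TSV", {
  m <- buildToyModel(seed = 1)
  tr <- runCVPulling(m, pullParams(duration = 0.05), seed = 2,
                     coreSasa = FALSE)$trace
  p <- tempfile(fileext = ".tsv")
  writeTraceTSV(tr, p)
  tr2 <- readTraceTSV(p)
  expect_equal(tr2@springK, tr@springK)
  expect_equal(traceData(tr2)$force_pN, traceData(tr)$force_pN,
               tolerance = 1e-9)
})

test_that("rupture force increases with pulling velocity", {
  peakAt <- function(v, dur, s) {
    m <- buildToyModel(seed = s)
    ev <- traceRupture(runCVPulling(m, pullParams(velocity = v,
                                                  duration = dur),
                                    seed = 300 + s)$trace)
    if (hasEvent(ev)) peakForce(ev) else NA_real_
  }
  seeds <- 1:6
  f1 <- vapply(seeds, function(s) peakAt(1, 8, s), numeric(1))
  f5 <- vapply(seeds, function(s) peakAt(5, 4, s), numeric(1))
  f25 <- vapply(seeds, function(s) peakAt(25, 1.2, s), numeric(1))
  expect_lt(mean(f1, na.rm = TRUE), mean(f5, na.rm = TRUE))
  expect_lt(mean(f5, na.rm = TRUE), mean(f25, na.rm = TRUE))
})
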
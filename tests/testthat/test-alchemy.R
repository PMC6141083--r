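# Alchemical machinery: schedules, soft core, sampler, EXP/BAR, cycle.

test_that("schedules span 0..1 uniformly with the protocol defaults", {
  s <- makeSchedule(100, 100, 0.5)
  expect_equal(s@lambdas[1], 0)
  expect_equal(s@lambdas[100], 1)
  expect_equal(unique(round(diff(s@lambdas), 12)), round(1 / 99, 12))
  expect_equal(s@nWindows * s@windowLength, 10000)  # 10 ns total
  expect_equal(makeSchedule(2, 1, 0.5)@lambdas, c(0, 1))
  expect_error(makeSchedule(1), class = "oxfold_domain_error")
  expect_error(makeSchedule(10, 1, 1.0), class = "oxfold_domain_error")
})

test_that("soft-core potential: endpoints, minimum, finiteness at r = 0", {
  expect_equal(softcorePotential(c(0, 1, 3), 0, 0.3, 4), c(0, 0, 0))
  # full coupling reduces to plain Lennard-Jones: minimum -eps at rmin
  expect_equal(softcorePotential(4, 1, 0.3, 4), -0.3, tolerance = 1e-12)
  # independent evaluation of the documented formula at r = 0
  eps <- 0.3; rmin <- 4; lam <- 0.5; alpha <- 0.5
  direct <- lam * 4 * eps * (1 / (alpha * (1 - lam))^2 -
                             1 / (alpha * (1 - lam)))
  expect_equal(softcorePotential(0, lam, eps, rmin, alpha), direct)
  expect_true(is.finite(softcorePotential(0, 0.999, eps, rmin, alpha)))
  # plain LJ at lam = 1 diverges at r -> 0; soft core must not for lam < 1
  expect_true(all(is.finite(softcorePotential(
    seq(0, 6, by = 0.1), 0.9, eps, rmin, alpha))))
})

test_that("sampler: identity system gives all-zero work; seeds reproduce", {
  sys <- identityAlchemicalSystem()
  sch <- makeSchedule(5, 10, 0.5)
  w <- sampleWindows(sys, sch, seed = 4)
  expect_true(all(abs(unlist(w@forward)) < 1e-12))
  expect_true(all(abs(unlist(w@backward)) < 1e-12))
  for (est in list(expEstimate(w, "forward"), expEstimate(w, "backward"),
                   barEstimate(w)))
    expect_equal(deltaG(est), 0, tolerance = 1e-12)
  # stiffening transformation has positive mean forward work
  sysH <- harmonicAlchemicalSystem(1, 4)
  wh <- sampleWindows(sysH, makeSchedule(10, 20, 0.5), seed = 5)
  expect_gt(mean(unlist(wh@forward)), 0)
  # bit-identical on repeat with the same seed
  wh2 <- sampleWindows(sysH, makeSchedule(10, 20, 0.5), seed = 5)
  expect_identical(wh@forward, wh2@forward)
  expect_identical(wh@backward, wh2@backward)
})

test_that("estimators are exact on delta-distributed work", {
  for (nw in c(1, 4)) {
    lam <- seq(0, 1, length.out = nw + 1)
    w0 <- 1.7 / nw
    w <- new("WorkData", forward = rep(list(rep(w0, 50)), nw),
             backward = rep(list(rep(-w0, 50)), nw),
             lambdas = lam, temperature = 300)
    expect_equal(deltaG(barEstimate(w)), 1.7, tolerance = 1e-7)
    expect_equal(standardError(barEstimate(w)), 0, tolerance = 1e-7)
    expect_equal(deltaG(expEstimate(w, "forward")), 1.7, tolerance = 1e-12)
    expect_equal(deltaG(expEstimate(w, "backward")), 1.7, tolerance = 1e-12)
  }
})

test_that("EXP recovers the Gaussian closed form", {
  # for delta-U ~ N(mu, sigma^2), EXP converges to mu - sigma^2 / (2 kT)
  kt <- kT(300)
  mu <- 1.2; sigma <- 0.5   # kcal/mol
  w <- withr::with_seed(21, new(
    "WorkData", forward = list(rnorm(1e4, mu, sigma)), backward = list(),
    lambdas = c(0, 1), temperature = 300))
  est <- expEstimate(w, "forward")
  expect_equal(deltaG(est), mu - sigma^2 / (2 * kt),
               tolerance = 3 * standardError(est) / abs(deltaG(est)))
  expect_gt(standardError(est), 0)
})

test_that("Crooks generator: moments, symmetry, determinism", {
  kt <- kT(300)
  g <- genCrooksSamples(3, 2, 5000, 5000, seed = 11)
  wf <- g$work@forward[[1]] / kt
  wb <- g$work@backward[[1]] / kt
  # stated Normals within 3 standard errors at n = 5000
  expect_equal(mean(wf), 3 + 2, tolerance = 3 * 2 / sqrt(5000) / 5)
  expect_equal(mean(wb), -3 + 2, tolerance = 3 * 2 / sqrt(5000))
  expect_equal(sd(wf), 2, tolerance = 0.1)
  # sigma = 0 degenerates to delta distributions
  g0 <- genCrooksSamples(1.5, 0, 100, 100, seed = 2)
  expect_true(all(g0$work@forward[[1]] / kt == 1.5))
  expect_true(all(g0$work@backward[[1]] / kt == -1.5))
  # seeded repeat is bit-identical
  expect_identical(genCrooksSamples(3, 2, 100, 100, seed = 9)$work@forward,
                   genCrooksSamples(3, 2, 100, 100, seed = 9)$work@forward)
  # dg = 0: forward and backward work distributions coincide in law
  gs <- genCrooksSamples(0, 1, 5000, 5000, seed = 13)
  ks <- suppressWarnings(stats::ks.test(gs$work@forward[[1]],
                                        gs$work@backward[[1]]))
  expect_gt(ks$p.value, 0.01)
})

test_that("EXP estimates bracket the truth in expectation; BAR is unbiased", {
  kt <- kT(300)
  ests <- t(vapply(1:40, function(s) {
    g <- genCrooksSamples(2, 2.5, 400, 400, seed = s)
    c(f = deltaG(expEstimate(g$work, "forward")) / kt,
      b = deltaG(expEstimate(g$work, "backward")) / kt,
      bar = deltaG(barEstimate(g$work)) / kt)
  }, numeric(3)))
  # small n + wide sigma: the one-sided biases emerge in the means
  expect_gt(mean(ests[, "f"]), 2)
  expect_lt(mean(ests[, "b"]), 2)
  expect_equal(mean(ests[, "bar"]), 2, tolerance = 0.1)
})

test_that("BAR is gauge-invariant under a constant shift of one window", {
  g <- genCrooksSamples(1, 1.5, 2000, 2000, seed = 3)
  base <- barEstimate(g$work)
  shifted <- g$work
  shifted@forward[[1]] <- shifted@forward[[1]] + 2.5
  shifted@backward[[1]] <- shifted@backward[[1]] - 2.5
  expect_equal(deltaG(barEstimate(shifted)), deltaG(base) + 2.5,
               tolerance = 1e-6)
})

test_that("harmonic system recovers the partition-function closed form", {
  sys <- harmonicAlchemicalSystem(1, 4, temperature = 300)
  expect_equal(sys@closedFormDg, 0.5 * kT(300) * log(4))
  expect_equal(sys@closedFormDg, 0.4132, tolerance = 1e-4)
  est <- runAlchemical(sys, makeSchedule(20, 50, 0.5), seed = 8)
  expect_equal(deltaG(est), sys@closedFormDg,
               tolerance = 2 * standardError(est) / sys@closedFormDg)
})

test_that("window splitting leaves the harmonic total consistent", {
  sys <- harmonicAlchemicalSystem(1, 4)
  coarse <- runAlchemical(sys, makeSchedule(10, 50, 0.5), seed = 14)
  fine <- runAlchemical(sys, makeSchedule(19, 50, 0.5), seed = 15)
  tol <- 2 * sqrt(standardError(coarse)^2 + standardError(fine)^2)
  expect_lt(abs(deltaG(coarse) - deltaG(fine)), tol)
})

test_that("soft-core insertion toy agrees with the quadrature reference", {
  sys <- siteAlchemicalSystem(c(-3.2, 3.2), label = "buried")
  est <- runAlchemical(sys, makeSchedule(40, 30, 0.5), seed = 6)
  expect_lt(abs(deltaG(est) - sys@closedFormDg), 2 * standardError(est))
  expect_gt(sys@closedFormDg, 0)
  # exposed neighbors make the transformation nearly free
  sysE <- siteAlchemicalSystem(c(-30, 30), label = "exposed")
  expect_lt(abs(sysE@closedFormDg), 0.02)
})

test_that("the thermodynamic cycle closes, negates and adds in quadrature", {
  f <- freeEnergyEstimate(5, 0.3)
  u <- freeEnergyEstimate(2, 0.4)
  r <- ddgCycle(f, u)
  expect_equal(deltaG(r), 3)
  expect_equal(standardError(r), 0.5)
  # identical environments close the cycle exactly
  expect_equal(deltaG(ddgCycle(f, f)), 0)
  # antisymmetry under swapping the legs
  expect_equal(deltaG(ddgCycle(u, f)), -deltaG(r))
  expect_error(ddgCycle(f, freeEnergyEstimate(2, 0.4, temperature = 310)),
               class = "oxfold_domain_error")
})

test_that("work data TSV round trips with temperature", {
  g <- genCrooksSamples(1, 0.5, 50, 40, seed = 5, temperature = 310)
  p <- tempfile(fileext = ".tsv")
  writeWorkDataTSV(g$work, p)
  w2 <- readWorkDataTSV(p)
  expect_equal(w2@temperature, 310)
  expect_equal(w2@forward, g$work@forward, tolerance = 1e-12)
  expect_equal(w2@backward, g$work@backward, tolerance = 1e-12)
  expect_equal(w2@lambdas, c(0, 1))
})
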
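# Replicate statistics: mean/SEM, one-tailed t-tests, tiers, summaries.

test_that("mean and SEM match hand computation and a high-precision oracle", {
  expect_equal(meanSem(c(2, 4, 6)), c(mean = 4, sem = 2 / sqrt(3)))
  expect_equal(meanSem(c(2, 4, 6))[["sem"]], 1.1547, tolerance = 1e-4)
  expect_equal(meanSem(rep(3.2, 5)), c(mean = 3.2, sem = 0))
  expect_error(meanSem(7), class = "oxfold_domain_error")
  withr::with_seed(31, {
    for (i in 1:50) {
      v <- rnorm(sample(2:20, 1), sd = runif(1, 0.1, 10))
      ms <- meanSem(v)
      expect_equal(ms[["mean"]], sum(v) / length(v), tolerance = 1e-12)
      expect_equal(ms[["sem"]],
                   sqrt(sum((v - mean(v))^2) / (length(v) - 1)) /
                     sqrt(length(v)), tolerance = 1e-12)
    }
  })
})

test_that("one-tailed t-test agrees with stats::t.test in both modes", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  p <- oneTailedT(a, b, "a_less")
  expect_equal(p, t.test(a, b, alternative = "less",
                         var.equal = TRUE)$p.value, tolerance = 1e-12)
  expect_lt(p, 0.05)
  # the spec'd oracle value: t = -3.674 on 4 df
  expect_equal(p, pt(-sqrt(4.5) / sqrt(1 / 3), 4), tolerance = 1e-12)
  # one-sided complement
  expect_equal(oneTailedT(a, b, "a_greater"), 1 - p, tolerance = 1e-12)
  # identical groups sit at the symmetric null
  expect_equal(oneTailedT(a, a, "a_less"), 0.5)
  # Welch mode against the base oracle
  withr::with_seed(5, {
    x <- rnorm(5); y <- rnorm(8, 1, 3)
    expect_equal(oneTailedT(x, y, "a_less", welch = TRUE),
                 t.test(x, y, alternative = "less")$p.value,
                 tolerance = 1e-12)
  })
  # degenerate zero-variance cases follow the documented convention
  expect_equal(oneTailedT(c(1, 1), c(1, 1), "a_less"), 0.5)
  expect_equal(oneTailedT(c(1, 1), c(2, 2), "a_less"), 0)
  expect_equal(oneTailedT(c(1, 1), c(2, 2), "a_greater"), 1)
})

test_that("tier classification follows the 0.05 / 0.10 thresholds", {
  expect_equal(classifyP(0.01), "significant")
  expect_equal(classifyP(0.07), "marginal")
  expect_equal(classifyP(0.5), "not_significant")
  # boundary grid: half-open intervals
  grid <- c(0, 0.049, 0.05, 0.0999, 0.10, 0.2, 1)
  expect_equal(classifyP(grid),
               c("significant", "significant", "marginal", "marginal",
                 "not_significant", "not_significant", "not_significant"))
  expect_error(classifyP(1.2), class = "oxfold_domain_error")
})

test_that("experiment summaries report means, SEMs, p-values and tiers", {
  withr::with_seed(17, {
    unox <- rnorm(10, 900, 40)
    ox <- rnorm(10, 700, 40)
    res <- summarizeExperiment(
      list(unoxidized = unox, oxidized = ox),
      design = list(reference = "unoxidized", alternative = "a_less",
                    unit = "pN"))
    expect_equal(nrow(res$conditions), 2L)
    expect_equal(res$conditions$mean[res$conditions$condition == "oxidized"],
                 mean(ox))
    cmp <- res$comparisons
    expect_equal(nrow(cmp), 1L)
    expect_equal(cmp$p_value, oneTailedT(ox, unox, "a_less"))
    expect_equal(cmp$tier, "significant")
    # identical data per condition: p = 0.5, not significant
    same <- summarizeExperiment(
      list(a = c(1, 2, 3), b = c(1, 2, 3)),
      design = list(reference = "a"))
    expect_equal(same$comparisons$p_value, 0.5)
    expect_equal(same$comparisons$tier, "not_significant")
    # constructed separation by 3 SDs is significant
    sep <- summarizeExperiment(
      list(ref = unox, low = unox - 3 * sd(unox)),
      design = list(reference = "ref", alternative = "a_less"))
    expect_equal(sep$comparisons$tier, "significant")
    expect_error(summarizeExperiment(list(a = 1:3), list(reference = "z")),
                 class = "oxfold_config_error")
  })
})

test_that("reports serialize to JSON, TSV and text", {
  res <- summarizeExperiment(
    list(unoxidized = c(900, 880, 930), oxidized = c(700, 760, 720)),
    design = list(reference = "unoxidized", alternative = "a_less",
                  unit = "pN"))
  dir <- tempfile()
  writeReport(res, dir)
  expect_true(all(file.exists(file.path(
    dir, c("report.json", "report.tsv", "report.txt")))))
  j <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_equal(j$design$reference, "unoxidized")
  expect_equal(length(j$conditions), 2L)
  tsv <- read.delim(file.path(dir, "report.tsv"))
  expect_equal(tsv$group_a, "oxidized")
})

test_that("summaries accept rupture events and ddG results as replicates", {
  mkEv <- function(f) new("RuptureEvent", event = TRUE, crossingTime = 100,
                          peakTime = 120, peakForce = f / pnPerKcalMolA,
                          peakForcePN = f, window = 400, threshold = 50)
  res <- summarizeExperiment(
    list(wt = list(mkEv(900), mkEv(950), mkEv(880)),
         ox = list(mkEv(600), mkEv(640), mkEv(610))),
    design = list(reference = "wt", alternative = "a_less"))
  expect_equal(res$comparisons$tier, "significant")
  dd <- lapply(c(3, 3.3), function(x)
    ddgCycle(freeEnergyEstimate(x + 2, 0.1), freeEnergyEstimate(2, 0.1)))
  res2 <- summarizeExperiment(
    list(buried = dd, exposed = list(0.05, -0.02)),
    design = list(reference = "exposed", alternative = "a_greater"))
  expect_equal(res2$conditions$mean[res2$conditions$condition == "buried"],
               3.15)
})
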
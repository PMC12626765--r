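strongModel <- function(seed, ...) {
  # strong mediator instruments so the screened signal is clearly
  # detectable against the rare-disease outcome noise
  triadModel(effectMRange = c(0.3, 0.5), seed = seed, ...)
}

test_that("step-1 screen recovers causal metabolites with a sound audit", {
  sim <- simulateMetabolome(strongModel(1001L), k = 10,
                            causalIds = c(3, 8))
  scr <- step1Screen(sim$metabolites, sim$outcome, sim$ld,
                     mrConfig(seed = 1L, nBoot = 0L), verbose = FALSE)
  expect_true(all(c("met03", "met08") %in% scr$survivors))
  st <- auditStages(scr$audit)
  expect_identical(st$stage[1:2], c("estimation", "ivw_significance"))
  # conservation at every stage and stage composition
  drops <- auditDrops(scr$audit)
  for (i in seq_len(nrow(st)))
    expect_identical(st$entering[i] - st$passing[i],
                     sum(drops$stage == st$stage[i]))
  expect_identical(st$entering[-1], st$passing[-nrow(st)])
  expect_identical(st$entering[1], 10L)
  expect_identical(st$passing[nrow(st)], length(scr$survivors))
})

test_that("contaminated metabolites are dropped at the matching stage", {
  # strong directional pleiotropy: dropped at the pleiotropy stage
  drops <- character()
  for (s in 1:8) {
    sim <- simulateMetabolome(
      strongModel(1100L + s, pleiotropyFrac = 0, hetInflation = 6),
      k = 1, causalIds = 1)
    scr <- step1Screen(sim$metabolites, sim$outcome, sim$ld,
                       mrConfig(seed = s, nBoot = 0L), verbose = FALSE)
    d <- auditDrops(scr$audit)
    drops <- c(drops, d$stage[d$trait == "met01"])
  }
  # inflated outcome variance shows up as heterogeneity (when the
  # trait is dropped at all, heterogeneity dominates the reasons)
  expect_gt(sum(drops == "heterogeneity"), 0)

  # fully reverse-causal trait: every apparent instrument is really an
  # outcome variant, so the forward arm looks clean and significant and
  # only the reverse stage can unmask it
  revDrops <- 0
  for (s in 1:8) {
    sim <- simulateMetabolome(
      strongModel(1200L + s, reverseFrac = 1, reverseEffect = 1),
      k = 1, causalIds = integer())
    scr <- step1Screen(sim$metabolites, sim$outcome, sim$ld,
                       mrConfig(seed = s, nBoot = 0L), verbose = FALSE)
    d <- auditDrops(scr$audit)
    if ("met01" %in% d$trait &&
        d$stage[d$trait == "met01"] == "reverse_causation")
      revDrops <- revDrops + 1
  }
  expect_gt(revDrops, 4)
})

test_that("directional pleiotropy is caught by the sensitivity filters", {
  # a causal metabolite whose instruments all carry an aligned direct
  # outcome effect: the Egger slope stays real (so the direction
  # filter can pass) while the intercept absorbs the bias
  pleioDrops <- 0; survived <- 0
  for (s in 1:8) {
    sim <- simulateMetabolome(
      strongModel(1250L + s, pleiotropyFrac = 1,
                  pleiotropyMean = 0.15, pleiotropySd = 0.02),
      k = 1, causalIds = 1)
    scr <- step1Screen(sim$metabolites, sim$outcome, sim$ld,
                       mrConfig(seed = s, nBoot = 0L), verbose = FALSE)
    d <- auditDrops(scr$audit)
    if (length(scr$survivors)) survived <- survived + 1
    if ("met01" %in% d$trait &&
        d$stage[d$trait == "met01"] == "pleiotropy")
      pleioDrops <- pleioDrops + 1
  }
  expect_gte(pleioDrops, 3)   # intercept test is the binding filter
  expect_lte(survived, 1)     # contaminated trait almost never passes
})

test_that("an empty screen and estimator failures stay well-formed", {
  sim <- simulateMetabolome(triadModel(seed = 1301L), k = 2)
  # absurd threshold: nothing has instruments -> estimation failures
  cfg <- mrConfig(seed = 1L, pThreshold = 1e-300, nBoot = 0L)
  scr <- step1Screen(sim$metabolites, sim$outcome, sim$ld, cfg,
                     verbose = FALSE)
  expect_length(scr$survivors, 0)
  st <- auditStages(scr$audit)
  expect_identical(st$passing[nrow(st)], 0L)
  expect_identical(sum(auditDrops(scr$audit)$stage == "estimation"), 2L)
  expect_length(scr$failReason, 2)
  # zero traits
  scr0 <- step1Screen(list(), sim$outcome, sim$ld,
                      mrConfig(seed = 1L, nBoot = 0L), verbose = FALSE)
  expect_length(scr0$survivors, 0)
})

test_that("step-2 screen recovers metabolites downstream of the exposure", {
  # a strong exposure -> metabolite effect (well-powered step-2 arm)
  sim <- simulateMetabolome(strongModel(1401L, a = 0.5,
                                        nInstrumentsE = 50L),
                            k = 6, causalIds = integer(),
                            exposureCausalIds = c(1, 5))
  cfg <- mrConfig(seed = 2L, pThreshold = 5e-8, nBoot = 0L)
  scr <- step2Screen(sim$exposure, sim$metabolites, sim$ld, cfg,
                     verbose = FALSE)
  expect_true(all(c("met01", "met05") %in% scr$survivors))
  # metabolites untouched by the exposure mostly do not survive
  expect_lt(length(setdiff(scr$survivors, c("met01", "met05"))), 3)
})

test_that("exposure-swap validation verdicts react to the simulated truth", {
  sim <- simulateTriad(triadModel(seed = 1501L))
  cfg <- mrConfig(seed = 3L, pThreshold = 5e-8, nBoot = 0L)
  v <- validateExposureSwap(sim$exposure, sim$mediator, sim$ld, cfg)
  expect_true(v$verdict$significant)
  expect_true(v$verdict$directionConsistent)
  # identical inputs give identical verdicts
  v2 <- validateExposureSwap(sim$exposure, sim$mediator, sim$ld, cfg)
  expect_identical(v$verdict, v2$verdict)
  # a null alternative exposure is not significant
  simNull <- simulateTriad(triadModel(a = 0, seed = 1502L))
  vn <- validateExposureSwap(simNull$exposure, simNull$mediator,
                             simNull$ld, cfg)
  expect_false(vn$verdict$significant)
})

test_that("optional BH mode only ever shrinks the survivor set", {
  sim <- simulateMetabolome(strongModel(1601L), k = 8,
                            causalIds = c(1, 2))
  cfg <- mrConfig(seed = 4L, nBoot = 0L)
  raw <- step1Screen(sim$metabolites, sim$outcome, sim$ld, cfg,
                     verbose = FALSE)
  bh <- step1Screen(sim$metabolites, sim$outcome, sim$ld, cfg,
                    padjust = "BH", verbose = FALSE)
  expect_true(all(bh$survivors %in% raw$survivors))
})
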
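test_that("Wald ratio arithmetic and degenerate cases", {
  e <- mrWaldRatio(data.frame(bx = 0.1, sx = 0.01, by = 0.2, sy = 0.05))
  expect_equal(e@beta, 2.0)
  expect_equal(e@se, 0.5)
  z <- mrWaldRatio(data.frame(bx = 0.1, sx = 0.01, by = 0, sy = 0.05))
  expect_identical(z@beta, 0)
  expect_identical(z@pvalue, 1)
  expect_error(mrWaldRatio(data.frame(bx = 0, sx = 0.01, by = 0.2,
                                      sy = 0.05)), "degenerate")
})

test_that("IVW reduces correctly in homogeneous and unit-weight cases", {
  # identical Wald ratios: beta is that ratio exactly
  d <- data.frame(bx = c(0.1, 0.2), sx = 0.01,
                  by = c(0.05, 0.10), sy = 0.03)
  expect_equal(mrIVW(d)@beta, 0.5, tolerance = 1e-14)
  # equal weights, bx all 1: reduces to mean(by)
  d2 <- data.frame(bx = 1, sx = 0.01, by = c(0.1, 0.3, 0.5), sy = 0.2)
  expect_equal(mrIVW(d2)@beta, 0.3, tolerance = 1e-14)
  # single instrument falls back to the Wald ratio with a message
  expect_message(
    e1 <- mrIVW(data.frame(bx = 0.1, sx = 0.01, by = 0.2, sy = 0.05)),
    "Wald")
  expect_identical(e1@method, "wald_ratio")
  expect_error(mrIVW(data.frame(bx = numeric(), sx = numeric(),
                                by = numeric(), sy = numeric())))
})

test_that("IVW matches the weighted-least-squares-through-origin oracle", {
  for (s in 1:5) {
    d <- makeInstruments(20, seed = 100 + s)
    d$sy <- runif(20, 0.02, 0.08)
    o <- oracle_ivw(d$bx, d$by, d$sy)
    fixed <- mrIVW(d, model = "fixed")
    rand <- mrIVW(d, model = "multiplicative_random")
    expect_equal(fixed@beta, o$beta, tolerance = 1e-10)
    expect_equal(fixed@se, o$seFixed, tolerance = 1e-10)
    expect_equal(rand@se, o$seRandom, tolerance = 1e-10)
    expect_gte(rand@se, fixed@se)   # floor at 1: never deflated
  }
  # IVW (fixed) equals the inverse-variance weighted mean of Wald
  # ratios with first-order variances
  d <- makeInstruments(15, seed = 77)
  theta <- d$by / d$bx
  v <- (d$sy / d$bx)^2
  expect_equal(mrIVW(d, model = "fixed")@beta,
               sum(theta / v) / sum(1 / v), tolerance = 1e-8)
})

test_that("Egger recovers a noiseless line and matches the regression oracle", {
  bx <- seq(0.05, 0.2, length.out = 6)
  d <- data.frame(bx = bx, sx = 0.01, by = 0.05 + 0.3 * bx, sy = 0.04)
  e <- mrEgger(d)
  expect_equal(e$slope@beta, 0.3, tolerance = 1e-10)
  expect_equal(e$intercept, 0.05, tolerance = 1e-10)
  # shifting all by by a constant moves the intercept only
  d2 <- d; d2$by <- d$by + 0.7
  e2 <- mrEgger(d2)
  expect_equal(e2$intercept, e$intercept + 0.7, tolerance = 1e-10)
  expect_equal(e2$slope@beta, e$slope@beta, tolerance = 1e-10)
  # generic weighted-regression oracle on noisy instruments (bx > 0 so
  # the internal re-orientation is a no-op)
  for (s in 1:5) {
    d <- makeInstruments(20, seed = 200 + s, bxRange = c(0.05, 0.2))
    d$bx <- abs(d$bx)
    d$sy <- runif(20, 0.02, 0.08)
    o <- oracle_egger(d$bx, d$by, d$sy)
    e <- mrEgger(d)
    expect_equal(e$slope@beta, o$beta, tolerance = 1e-10)
    expect_equal(e$slope@se, o$se, tolerance = 1e-10)
    expect_equal(e$intercept, o$intercept, tolerance = 1e-10)
    expect_equal(e$interceptSe, o$interceptSe, tolerance = 1e-10)
  }
  expect_error(mrEgger(makeInstruments(2, seed = 1)), ">= 3")
})

test_that("weighted median interpolates correctly and bootstraps reproducibly", {
  # symmetric equal-weight case
  d <- data.frame(bx = 1, sx = 0.01, by = c(1, 2, 3), sy = 1)
  expect_equal(mrWeightedMedian(d, nBoot = 0)@beta, 2)
  # dominant weight pulls the median onto its own ratio
  d2 <- data.frame(bx = c(1, 1, 2), sx = 0.01, by = c(1, 3, 4),
                   sy = c(1, 1, 1))  # weights 1,1,4 -> ratios 1,3,2
  expect_equal(mrWeightedMedian(d2, nBoot = 0)@beta, 2)
  # interpolation oracle on random sets
  for (s in 1:5) {
    d <- makeInstruments(15, seed = 300 + s)
    d$sy <- runif(15, 0.02, 0.08)
    got <- mrWeightedMedian(d, nBoot = 0)@beta
    expect_equal(got, oracle_weighted_median(d$by / d$bx,
                                             d$bx^2 / d$sy^2),
                 tolerance = 1e-10)
  }
  # bootstrap SE is seed-reproducible and changes with the seed
  d <- makeInstruments(15, seed = 33)
  a <- mrWeightedMedian(d, nBoot = 200, seed = 5)
  b <- mrWeightedMedian(d, nBoot = 200, seed = 5)
  c2 <- mrWeightedMedian(d, nBoot = 200, seed = 6)
  expect_identical(a@se, b@se)
  expect_false(identical(a@se, c2@se))
})

test_that("mode estimators find the dominant cluster, not the mean", {
  d <- data.frame(bx = 1, sx = 0.01, by = c(0.99, 1.0, 1.01, 5.0),
                  sy = 0.05)
  m <- mrMode(d, weighted = FALSE, nBoot = 0)
  expect_lt(abs(m@beta - 1), 0.1)
  # degenerate cluster: all ratios identical
  d0 <- data.frame(bx = c(1, 2, 4), sx = 0.01, by = c(0.5, 1, 2),
                   sy = 0.05)
  expect_equal(mrMode(d0, weighted = FALSE, nBoot = 0)@beta, 0.5)
  # dense-grid density-argmax oracle, within grid resolution
  for (s in 1:3) {
    d <- makeInstruments(25, seed = 400 + s)
    d$sy <- runif(25, 0.02, 0.08)
    theta <- d$by / d$bx
    hGrid <- 0.9 * min(sd(theta), mad(theta)) * 25^(-1 / 5)
    res <- diff(range(theta) + c(-3, 3) * hGrid) / 511
    for (weighted in c(FALSE, TRUE)) {
      w <- if (weighted) d$bx^2 / d$sy^2 else rep(1, 25)
      got <- mrMode(d, weighted = weighted, nBoot = 0)@beta
      expect_equal(got, oracle_mode(theta, w), tolerance = 2 * res)
    }
  }
  # bootstrap reproducibility
  d <- makeInstruments(12, seed = 55)
  expect_identical(mrMode(d, nBoot = 100, seed = 3)@se,
                   mrMode(d, nBoot = 100, seed = 3)@se)
})

test_that("Cochran's Q matches hand formulas and its null distribution", {
  # identical ratios: Q = 0, p = 1
  d0 <- data.frame(bx = c(1, 2), sx = 0.01, by = c(0.5, 1), sy = 0.05)
  q0 <- cochranQ(d0)
  expect_equal(q0$qStat, 0, tolerance = 1e-20)
  expect_equal(q0$qPvalue, 1)
  expect_identical(q0$qDf, 1L)
  # closed form for two instruments:
  # Q = (theta1 - theta2)^2 / (v1 + v2)
  d2 <- data.frame(bx = c(0.1, 0.2), sx = 0.01, by = c(0.05, 0.02),
                   sy = c(0.03, 0.04))
  theta <- d2$by / d2$bx
  v <- (d2$sy / d2$bx)^2
  expect_equal(cochranQ(d2)$qStat, diff(theta)^2 / sum(v),
               tolerance = 1e-12)
  expect_error(cochranQ(d0[1, ]), ">= 2")
  # simulation oracle: homogeneous sets give E[Q] ~ J - 1
  set.seed(12)
  J <- 8
  qs <- replicate(2000, {
    bx <- runif(J, 0.05, 0.15)
    sy <- runif(J, 0.02, 0.08)
    by <- 0.4 * bx + rnorm(J, 0, sy)
    cochranQ(data.frame(bx = bx, sx = 0.001, by = by, sy = sy))$qStat
  })
  expect_lt(abs(mean(qs) - (J - 1)), 0.25)  # MC error ~ 0.08
})

test_that("direction consistency demands a strict shared sign", {
  expect_true(directionConsistent(c(0.3, 0.2, 0.25, 0.1, 0.4)))
  expect_false(directionConsistent(c(0.3, -0.01, 0.25, 0.1, 0.4)))
  expect_false(directionConsistent(c(0.3, 0, 0.2, 0.1, 0.4)))
  expect_true(directionConsistent(c(-0.3, -0.01, -0.2, -0.1, -0.4)))
  expect_error(directionConsistent(c(0.3, NA, 0.2, 0.1, 0.4)), "missing")
})

test_that("the full battery recovers a known effect and skips nothing", {
  sim <- simulateTriad(triadModel(seed = 31L))
  cfg <- mrConfig(seed = 9L, nBoot = 50L)
  b <- runMRBattery(sim$exposure, sim$mediator, sim$ld, cfg)
  est <- estimates(b)
  expect_identical(est$method,
                   c("ivw", "egger", "weighted_median", "simple_mode",
                     "weighted_mode"))
  ivw <- est[est$method == "ivw", ]
  expect_true(ivw$ci_low < 0.2 && 0.2 < ivw$ci_high)
  s <- sensitivity(b)
  expect_identical(s@qDf, as.integer(ivw$n_snps) - 1L)
  expect_gte(s@qStat, 0)
  # binary outcome populates odds-ratio fields
  bo <- runMRBattery(sim$exposure, sim$outcome, sim$ld, cfg)
  eo <- estimates(bo)
  expect_equal(eo$or, exp(eo$beta))
  # determinism: identical config + seed -> identical output
  b2 <- runMRBattery(sim$exposure, sim$mediator, sim$ld, cfg)
  expect_identical(estimates(b2), estimates(b))
})

test_that("reverse-causal data trip the reverse arm", {
  # mediator generated downstream of the outcome: reverse MR
  # (outcome -> mediator) should show a clear signal
  hits <- replicate(20, NA)
  for (s in 1:20) {
    sim <- simulateTriad(triadModel(a = 0, b = 0, reverseFrac = 0.4,
                                    reverseEffect = 0.4,
                                    seed = 600 + s))
    b <- tryCatch(
      runMRBattery(sim$mediator, sim$outcome, sim$ld,
                   mrConfig(seed = s, nBoot = 0L)),
      error = function(e) NULL)
    if (!is.null(b)) hits[s] <- sensitivity(b)@reversePvalue < 0.05
  }
  expect_gt(mean(hits, na.rm = TRUE), 0.8)
})
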
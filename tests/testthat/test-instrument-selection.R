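test_that("p-value selection uses a strict threshold and preserves order", {
  s <- makeSumStats(n = 3, pval = c(1e-6, 2e-5, 0.03))
  expect_identical(records(selectByPvalue(s, 1e-5))$variant_id, "rs1")
  expect_identical(nVariants(selectByPvalue(s, 1 - 1e-12)), 3L)
  # brute-force scan oracle on a larger table
  set.seed(3)
  big <- makeSumStats(n = 10000, pval = 10^-runif(10000, 0, 10))
  got <- records(selectByPvalue(big, 5e-8))$variant_id
  want <- records(big)$variant_id[records(big)$pval < 5e-8]
  expect_identical(got, want)
})

test_that("clumping keeps the lowest-p variant of a dependent pair", {
  s <- makeSumStats(n = 2, pos = c(1e6, 6e6), pval = c(1e-8, 1e-10))
  ld <- ldSource(data.frame(id_a = "rs1", id_b = "rs2", r2 = 0.5),
                 domain = c("rs1", "rs2"))
  kept <- clumpInstruments(s, ld, r2Max = 0.001, windowBp = 1e7)
  expect_identical(records(kept)$variant_id, "rs2")
  # different chromosomes: the window never spans them
  s2 <- makeSumStats(n = 2, chr = c("1", "2"), pos = c(1e6, 1e6),
                     pval = c(1e-8, 1e-10))
  expect_identical(nVariants(clumpInstruments(s2, ld)), 2L)
})

test_that("clumping matches the exhaustive greedy oracle and is order-invariant", {
  set.seed(42)
  n <- 50
  ids <- paste0("rs", 1:n)
  df <- data.frame(variant_id = ids, chr = sample(c("1", "2"), n, TRUE),
                   pos = sample.int(3e7, n), ea = "A", oa = "G",
                   eaf = 0.3, beta = 0.1, se = 0.01,
                   pval = 10^-runif(n, 4, 12), n = 1e4)
  r2mat <- matrix(0, n, n, dimnames = list(ids, ids))
  pairs <- t(combn(ids, 2))
  hot <- sample.int(nrow(pairs), 300)
  vals <- runif(length(hot))
  pairsDf <- data.frame(id_a = pairs[hot, 1], id_b = pairs[hot, 2],
                        r2 = vals)
  for (i in seq_along(hot)) {
    r2mat[pairsDf$id_a[i], pairsDf$id_b[i]] <- pairsDf$r2[i]
    r2mat[pairsDf$id_b[i], pairsDf$id_a[i]] <- pairsDf$r2[i]
  }
  diag(r2mat) <- 1
  ld <- ldSource(pairsDf, domain = ids)
  s <- SumStats(df, verbose = FALSE)
  got <- sort(records(clumpInstruments(s, ld, 0.1, 1e7))$variant_id)
  want <- sort(oracle_clump(df, r2mat, 0.1, 1e7))
  expect_identical(got, want)
  # permuting input record order leaves the retained set unchanged
  perm <- SumStats(df[sample.int(n), ], verbose = FALSE)
  gotPerm <- sort(records(clumpInstruments(perm, ld, 0.1, 1e7))$variant_id)
  expect_identical(gotPerm, want)
})

test_that("variants outside the LD domain are treated as independent with a warning", {
  s <- makeSumStats(n = 2, pos = c(1e6, 2e6), pval = c(1e-8, 1e-9))
  ld <- ldSource(domain = "rs1")
  expect_warning(kept <- clumpInstruments(s, ld), "LD domain")
  expect_identical(nVariants(kept), 2L)
})

test_that("variance explained follows the printed formula and its algebraic short form", {
  expect_identical(varianceExplained(0, 0.3, 0.01, 100), 0)
  # symmetry in eaf <-> 1 - eaf with the sign of beta flipped
  expect_equal(varianceExplained(0.1, 0.3, 0.01, 1e4),
               varianceExplained(-0.1, 0.7, 0.01, 1e4))
  # plug-in oracle: evaluate the full printed form directly
  b <- 0.1; f <- 0.3; se <- 0.01; n <- 1e4
  num <- 2 * b^2 * f * (1 - f)
  long <- num / (num + 2 * se^2 * n * f * (1 - f))
  expect_equal(varianceExplained(b, f, se, n), long, tolerance = 1e-15)
  # property: long and short forms agree on a random grid to 1e-12
  set.seed(7)
  for (i in 1:200) {
    b <- rnorm(1, 0, 0.2); f <- runif(1, 0.01, 0.99)
    se <- runif(1, 1e-4, 0.1); n <- sample(100:1e6, 1)
    num <- 2 * b^2 * f * (1 - f)
    long <- num / (num + 2 * se^2 * n * f * (1 - f))
    expect_equal(varianceExplained(b, f, se, n), long,
                 tolerance = 1e-12)
  }
})

test_that("F-statistic formula, bounds and monotonicity hold", {
  expect_identical(fStatistic(0, 100), 0)
  expect_equal(fStatistic(0.5, 4), 2)     # 0.5 * 2 / 0.5
  expect_error(fStatistic(1, 100), "r2")
  # monotone in r2 at fixed n and in n at fixed r2, over a grid
  r2 <- seq(0, 0.9, by = 0.05)
  for (n in c(10, 100, 1e4))
    expect_true(all(diff(fStatistic(r2, n)) > 0))
  for (r in c(0.01, 0.1, 0.5))
    expect_true(all(diff(fStatistic(r, c(10, 100, 1e3, 1e5))) > 0))
})

test_that("weak-instrument filter is strict and matches a brute-force scan", {
  s <- makeSumStats(n = 3)
  met <- data.frame(variant_id = paste0("rs", 1:3), r2 = 0.1,
                    f_stat = c(9.9, 10, 10.1))
  expect_identical(records(filterWeak(s, met, 10))$variant_id, "rs3")
  expect_identical(nVariants(filterWeak(s, met, 5)), 3L)
  expect_error(filterWeak(s, met[-2, ], 10), "rs2")
  set.seed(5)
  big <- makeSumStats(n = 200, beta = rnorm(200, 0, 0.05),
                      eaf = runif(200, 0.05, 0.95),
                      se = runif(200, 0.005, 0.02))
  m <- instrumentMetrics(big)
  got <- records(filterWeak(big, m, 10))$variant_id
  expect_identical(got, m$variant_id[m$f_stat > 10])
})

test_that("the select-clump-filter pipeline never increases record counts", {
  sim <- simulateTriad(triadModel(seed = 5L))
  s <- sim$exposure
  sel <- selectByPvalue(s, 1e-5)
  cl <- clumpInstruments(sel, sim$ld)
  fw <- filterWeak(cl, instrumentMetrics(cl), 10)
  counts <- c(nVariants(s), nVariants(sel), nVariants(cl), nVariants(fw))
  expect_true(all(diff(counts) <= 0))
  expect_gte(nVariants(fw), 3L)
})
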
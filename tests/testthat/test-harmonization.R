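harmPair <- function(eaX, oaX, eaY, oaY, eafX = 0.3, eafY = 0.3,
                     by = 0.2, policy = harmonizationPolicy()) {
  ex <- makeSumStats(n = 1, ea = eaX, oa = oaX, eaf = eafX,
                     traitName = "exposure")
  out <- makeSumStats(n = 1, ea = eaY, oa = oaY, eaf = eafY, beta = by,
                      traitName = "outcome")
  harmonize(ex, out, policy)@instruments
}

test_that("direct matches, swaps, strand flips and mismatches act as documented", {
  r <- harmPair("A", "G", "A", "G")
  expect_identical(r$action, "kept_same")
  expect_identical(r$by, 0.2)

  r <- harmPair("A", "G", "G", "A", eafY = 0.3)
  expect_identical(r$action, "kept_flipped")
  expect_identical(r$by, -0.2)
  expect_equal(r$eafy, 0.7)

  r <- harmPair("A", "G", "T", "C")          # complement, same order
  expect_identical(r$action, "kept_strand_flipped")
  expect_identical(r$by, 0.2)

  r <- harmPair("A", "G", "C", "T")          # complement + swap
  expect_identical(r$action, "kept_strand_flipped")
  expect_identical(r$by, -0.2)

  r <- harmPair("A", "G", "A", "C")
  expect_identical(r$action, "dropped_mismatch")
  expect_true(is.na(r$by) && is.na(r$bx))    # no effect fields

  noStrand <- harmonizationPolicy(allowStrandFlip = FALSE)
  r <- harmPair("A", "G", "T", "C", policy = noStrand)
  expect_identical(r$action, "dropped_mismatch")
})

test_that("palindromic variants resolve by frequency or drop per policy", {
  # ambiguous frequency: dropped whatever the other side shows
  r <- harmPair("A", "T", "A", "T", eafX = 0.50, eafY = 0.2)
  expect_identical(r$action, "dropped_palindromic")
  # clear frequencies on the same side: kept as-is
  r <- harmPair("A", "T", "A", "T", eafX = 0.2, eafY = 0.25)
  expect_identical(r$action, "kept_same")
  # clear frequencies on opposite sides: strand flip implied
  r <- harmPair("A", "T", "A", "T", eafX = 0.2, eafY = 0.8)
  expect_identical(r$action, "kept_flipped")
  expect_identical(r$by, -0.2)
  # drop_all policy drops even resolvable palindromes
  r <- harmPair("C", "G", "C", "G", eafX = 0.2, eafY = 0.2,
                policy = harmonizationPolicy("drop_all"))
  expect_identical(r$action, "dropped_palindromic")
  # missing frequency cannot be resolved
  r <- harmPair("A", "T", "A", "T", eafX = NA, eafY = 0.2)
  expect_identical(r$action, "dropped_palindromic")
})

test_that("500 randomized pairs reproduce the enumerated rule table", {
  set.seed(99)
  alleles <- c("A", "C", "G", "T")
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  for (i in 1:500) {
    eaX <- sample(alleles, 1)
    oaX <- sample(setdiff(alleles, eaX), 1)
    config <- sample(c("same", "swap", "strand", "strand_swap",
                       "mismatch"), 1)
    pair <- switch(config,
      same = c(eaX, oaX), swap = c(oaX, eaX),
      strand = comp[c(eaX, oaX)], strand_swap = comp[c(oaX, eaX)],
      mismatch = { a <- sample(alleles, 1)
                   c(a, sample(setdiff(alleles, a), 1)) })
    eafX <- runif(1, 0.05, 0.95)
    eafY <- runif(1, 0.05, 0.95)
    want <- oracle_harmonize_pair(eaX, oaX, pair[1], pair[2], eafX, eafY)
    got <- harmPair(eaX, oaX, pair[1], pair[2], eafX = eafX, eafY = eafY)
    expect_identical(got$action, want$action,
                     label = paste(config, eaX, oaX, pair[1], pair[2]))
    if (want$action %in% c("kept_same", "kept_flipped",
                           "kept_strand_flipped"))
      expect_identical(got$by, if (want$flip) -0.2 else 0.2)
  }
})

test_that("instruments are fully accounted for and re-harmonization is idempotent", {
  sim <- simulateTriad(triadModel(seed = 8L))
  instruments <- selectInstruments(sim$exposure, sim$ld, 1e-5)
  h <- harmonize(instruments, sim$outcome)
  ins <- h@instruments
  expect_identical(nrow(ins), nVariants(instruments))
  expect_identical(nrow(keptInstruments(h)) + nrow(droppedInstruments(h)),
                   nrow(ins))
  # rebuild both traits from the harmonized pairs (shared orientation)
  k <- keptInstruments(h)
  rec <- records(instruments)
  rec <- rec[match(k$variant_id, rec$variant_id), ]
  outDf <- data.frame(variant_id = k$variant_id, chr = rec$chr,
                      pos = rec$pos, ea = rec$ea, oa = rec$oa,
                      eaf = k$eafy, beta = k$by, se = k$sy,
                      pval = k$py, n = 1000)
  out2 <- SumStats(outDf, traitName = "outcome2", verbose = FALSE)
  ex2 <- SumStats(cbind(rec[, c("variant_id", "chr", "pos", "ea", "oa")],
                        eaf = k$eafx, beta = k$bx, se = k$sx,
                        pval = k$px, n = 1000),
                  verbose = FALSE)
  h2 <- harmonize(ex2, out2)
  k2 <- keptInstruments(h2)
  expect_true(all(k2$action == "kept_same"))
  expect_equal(k2$by, k$by[match(k2$variant_id, k$variant_id)])
})

test_that("joint sign flips leave estimators unchanged; raw Egger is flagged", {
  d <- makeInstruments(10, seed = 21)
  d$variant_id <- paste0("iv", 1:10)
  hset <- new("HarmonizedSet",
              instruments = data.frame(variant_id = d$variant_id,
                                       action = "kept_same", bx = d$bx,
                                       sx = d$sx, px = 1e-8, eafx = 0.3,
                                       by = d$by, sy = d$sy, py = 0.01,
                                       eafy = 0.3))
  chk <- orientationInvarianceCheck(hset, seed = 4L)
  expect_true(as.logical(chk))
  expect_true(is.logical(attr(chk, "egger_raw_sensitive")))
  # single-instrument wald ratio invariance
  w1 <- mrWaldRatio(data.frame(bx = 0.1, sx = 0.01, by = 0.2, sy = 0.05))
  w2 <- mrWaldRatio(data.frame(bx = -0.1, sx = 0.01, by = -0.2, sy = 0.05))
  expect_identical(w1@beta, w2@beta)
  # IVW under whole-pair sign flips, to numerical precision
  flip <- rep(c(1, -1), 5)
  d2 <- within(d, { bx <- bx * flip; by <- by * flip })
  expect_equal(mrIVW(d)@beta, mrIVW(d2)@beta, tolerance = 1e-12)
})
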
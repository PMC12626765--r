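#' Construct a TriadModel
#'
#' Parameters of the synthetic exposure -> mediator -> outcome GWAS
#' generator. Defaults encode the study conditions the package's tests
#' and validation simulations run under: a UK-Biobank-scale continuous
#' adiposity exposure (n = 330,762; per-instrument effects 0.02-0.06
#' SD), a CLSA-scale circulating-metabolite mediator (n = 8,299;
#' effects 0.08-0.20 SD), and a FinnGen-scale binary outcome (855 cases
#' among 345,973 participants; instrument effects 0.20-0.45 log-odds),
#' with true causal chain a = 0.2, b = 0.3 and direct effect 0.3, so
#' the true total effect is 0.36 and the true mediated proportion
#' 0.06/0.36 = 16.7%. Contamination channels (directional pleiotropy,
#' excess heterogeneity, reverse-causal instruments) are off by
#' default.
#'
#' @param nVariants,nInstrumentsE,nInstrumentsM,nInstrumentsO,mafRange,effectERange,effectMRange,effectORange,a,b,cDirect,pleiotropyFrac,pleiotropyMean,pleiotropySd,hetInflation,reverseFrac,reverseEffect,nE,nM,nO,outcomeBinary,caseFrac,palindromeFrac,ldBlockSize,ldBlockR2,seed see [TriadModel-class].
#' @return a validated [TriadModel-class] object.
#' @export
triadModel <- function(nVariants = 400L, nInstrumentsE = 30L,
                       nInstrumentsM = 15L, nInstrumentsO = 10L,
                       mafRange = c(0.05, 0.5),
                       effectERange = c(0.02, 0.06),
                       effectMRange = c(0.08, 0.20),
                       effectORange = c(0.20, 0.45),
                       a = 0.2, b = 0.3, cDirect = 0.3,
                       pleiotropyFrac = 0, pleiotropyMean = 0,
                       pleiotropySd = 0.15, hetInflation = 1,
                       reverseFrac = 0, reverseEffect = 0.3,
                       nE = 330762, nM = 8299, nO = 345973,
                       outcomeBinary = TRUE, caseFrac = 855 / 345973,
                       palindromeFrac = 0.1,
                       ldBlockSize = 1L, ldBlockR2 = 0.5, seed = 1L) {
  new("TriadModel",
      nVariants = as.integer(nVariants),
      nInstrumentsE = as.integer(nInstrumentsE),
      nInstrumentsM = as.integer(nInstrumentsM),
      nInstrumentsO = as.integer(nInstrumentsO),
      mafRange = mafRange, effectERange = effectERange,
      effectMRange = effectMRange, effectORange = effectORange,
      a = a, b = b, cDirect = cDirect,
      pleiotropyFrac = pleiotropyFrac, pleiotropyMean = pleiotropyMean,
      pleiotropySd = pleiotropySd, hetInflation = hetInflation,
      reverseFrac = reverseFrac, reverseEffect = reverseEffect,
      nE = nE, nM = nM, nO = nO, outcomeBinary = outcomeBinary,
      caseFrac = caseFrac, palindromeFrac = palindromeFrac,
      ldBlockSize = as.integer(ldBlockSize), ldBlockR2 = ldBlockR2,
      seed = as.integer(seed))
}

setMethod("show", "TriadModel", function(object) {
  cat("TriadModel: ", object@nVariants, " variants; instruments E/M/O = ",
      object@nInstrumentsE, "/", object@nInstrumentsM, "/",
      object@nInstrumentsO, "\n",
      "  chain a = ", object@a, ", b = ", object@b, ", direct = ",
      object@cDirect, " (total ", object@a * object@b + object@cDirect,
      ")\n  seed ", object@seed, "\n", sep = "")
})

# GWAS standard error of a per-allele effect at allele frequency f.
# Binary traits use the effective sample size 4 v (1 - v) N.
.gwasSe <- function(n, maf, binary = FALSE, caseFrac = NA) {
  nEff <- if (binary) 4 * caseFrac * (1 - caseFrac) * n else n
  1 / sqrt(2 * nEff * maf * (1 - maf))
}

.NONPAL_PAIRS <- rbind(
  c("A", "C"), c("C", "A"), c("A", "G"), c("G", "A"),
  c("T", "C"), c("C", "T"), c("T", "G"), c("G", "T"))
.PAL_PAIRS <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

# Draw the shared variant panel: ids, positions, frequencies, alleles.
.drawPanel <- function(n, mafRange, palindromeFrac, seed) {
  .withSeed(seed, {
    maf <- stats::runif(n, mafRange[1], mafRange[2])
    pal <- stats::runif(n) < palindromeFrac
    idxPal <- sample.int(4L, n, replace = TRUE)
    idxNon <- sample.int(8L, n, replace = TRUE)
    ea <- ifelse(pal, .PAL_PAIRS[idxPal, 1], .NONPAL_PAIRS[idxNon, 1])
    oa <- ifelse(pal, .PAL_PAIRS[idxPal, 2], .NONPAL_PAIRS[idxNon, 2])
    data.frame(variant_id = paste0("sv", seq_len(n)), chr = "1",
               pos = seq_len(n) * 1e5, ea = ea, oa = oa, eaf = maf,
               stringsAsFactors = FALSE)
  })
}

# Observed GWAS layer for one trait: true effects + sampling noise.
.observeTrait <- function(panel, trueBeta, n, seed, binary = FALSE,
                          caseFrac = NA, noiseInflation = 1) {
  se <- .gwasSe(n, panel$eaf, binary = binary, caseFrac = caseFrac)
  beta <- .withSeed(seed,
                    trueBeta + stats::rnorm(nrow(panel)) * se *
                      sqrt(noiseInflation))
  pval <- pmax(2 * stats::pnorm(-abs(beta / se)), .Machine$double.xmin)
  cbind(panel, beta = beta, se = se, pval = pval, n = n)
}

# Randomly re-express some records (allele swap / strand complement)
# so harmonization is exercised; the represented association is
# unchanged.
.scrambleRepresentation <- function(rec, seed) {
  .withSeed(seed, {
    n <- nrow(rec)
    u <- stats::runif(n)
    swap <- u < 0.3
    pal <- .isPalindromic(rec$ea, rec$oa)
    strand <- u >= 0.3 & u < 0.45 & !pal
    tmp <- rec$ea[swap]
    rec$ea[swap] <- rec$oa[swap]
    rec$oa[swap] <- tmp
    rec$beta[swap] <- -rec$beta[swap]
    rec$eaf[swap] <- 1 - rec$eaf[swap]
    rec$ea[strand] <- .complementAllele(rec$ea[strand])
    rec$oa[strand] <- .complementAllele(rec$oa[strand])
    rec
  })
}

.blockLD <- function(ids, blockSize, r2) {
  if (blockSize <= 1L)
    return(ldSource(domain = ids))
  block <- (seq_along(ids) - 1L) %/% blockSize
  pairs <- do.call(rbind, lapply(split(ids, block), function(b) {
    if (length(b) < 2L) return(NULL)
    cmb <- utils::combn(b, 2L)
    data.frame(id_a = cmb[1, ], id_b = cmb[2, ], r2 = r2,
               stringsAsFactors = FALSE)
  }))
  if (is.null(pairs)) ldSource(domain = ids) else ldSource(pairs, ids)
}

#' Simulate a GWAS summary-statistics triad with known causal structure
#'
#' Generates exposure, mediator and outcome summary statistics under
#' the causal chain encoded in a [TriadModel-class]: per-variant true
#' effects are drawn for each instrument set, propagated along
#' exposure -> mediator -> outcome (direct effect `cDirect`, mediated
#' path `a * b`), contaminated per the model's pleiotropy /
#' heterogeneity / reverse-causation channels, and observed with
#' sampling noise `se = 1 / sqrt(2 N_eff f (1 - f))`. All randomness
#' derives from the model seed through named substreams, so identical
#' models give bit-identical output. Mediator and outcome records are
#' randomly re-expressed (allele swaps, strand complements) to
#' exercise harmonization.
#'
#' @param model a [TriadModel-class] object.
#' @return list with elements `exposure`, `mediator`, `outcome`
#'   ([SumStats-class]), `ld` (an [LDSource-class]; all variants
#'   independent unless the model sets LD blocks), and `truth` (per-
#'   variant roles and true effects plus the model's causal
#'   parameters).
#' @export
simulateTriad <- function(model) {
  stopifnot(is(model, "TriadModel"))
  validObject(model)
  n <- model@nVariants
  panel <- .drawPanel(n, model@mafRange, model@palindromeFrac,
                      .subSeed(model@seed, 1L))

  nRev <- round(model@reverseFrac * model@nInstrumentsM)
  nMed <- model@nInstrumentsM - nRev
  role <- rep("null", n)
  role[seq_len(model@nInstrumentsE)] <- "exposure_iv"
  role[model@nInstrumentsE + seq_len(nMed)] <- "mediator_iv"
  if (nRev > 0)
    role[model@nInstrumentsE + nMed + seq_len(nRev)] <- "reverse_iv"
  role[model@nInstrumentsE + nMed + nRev +
         seq_len(model@nInstrumentsO)] <- "outcome_iv"

  eff <- .withSeed(.subSeed(model@seed, 2L), {
    rsign <- function(k) sample(c(-1, 1), k, replace = TRUE)
    runifIn <- function(k, r) stats::runif(k, r[1], r[2])
    bE <- bM <- bO <- numeric(n)
    iE <- role == "exposure_iv"
    alpha <- rsign(sum(iE)) * runifIn(sum(iE), model@effectERange)
    bE[iE] <- alpha
    bM[iE] <- model@a * alpha
    bO[iE] <- (model@cDirect + model@a * model@b) * alpha
    nPleio <- round(model@pleiotropyFrac * sum(iE))
    if (nPleio > 0) {
      # directional pleiotropy rides the exposure-increasing allele:
      # aligned with each instrument's orientation so it survives the
      # bx >= 0 re-orientation MR-Egger applies
      who <- which(iE)[sample.int(sum(iE), nPleio)]
      bO[who] <- bO[who] + sign(bE[who]) *
        stats::rnorm(nPleio, model@pleiotropyMean, model@pleiotropySd)
    }
    iM <- role == "mediator_iv"
    gamma <- rsign(sum(iM)) * runifIn(sum(iM), model@effectMRange)
    bM[iM] <- gamma
    bO[iM] <- model@b * gamma
    iR <- role == "reverse_iv"
    if (any(iR)) {
      delta <- rsign(sum(iR)) * runifIn(sum(iR), model@effectORange)
      bO[iR] <- delta
      bM[iR] <- model@reverseEffect * delta
    }
    iO <- role == "outcome_iv"
    bO[iO] <- rsign(sum(iO)) * runifIn(sum(iO), model@effectORange)
    list(bE = bE, bM = bM, bO = bO)
  })

  recE <- .observeTrait(panel, eff$bE, model@nE, .subSeed(model@seed, 3L))
  recM <- .observeTrait(panel, eff$bM, model@nM, .subSeed(model@seed, 4L))
  recO <- .observeTrait(panel, eff$bO, model@nO, .subSeed(model@seed, 5L),
                        binary = model@outcomeBinary,
                        caseFrac = model@caseFrac,
                        noiseInflation = model@hetInflation)
  recM <- .scrambleRepresentation(recM, .subSeed(model@seed, 6L))
  recO <- .scrambleRepresentation(recO, .subSeed(model@seed, 7L))

  truth <- list(
    variants = data.frame(variant_id = panel$variant_id, role = role,
                          true_beta_exposure = eff$bE,
                          true_beta_mediator = eff$bM,
                          true_beta_outcome = eff$bO,
                          stringsAsFactors = FALSE),
    params = list(a = model@a, b = model@b, cDirect = model@cDirect,
                  totalEffect = model@a * model@b + model@cDirect,
                  proportion = model@a * model@b /
                    (model@a * model@b + model@cDirect),
                  seed = model@seed))

  list(exposure = SumStats(recE, "exposure", "continuous", verbose = FALSE),
       mediator = SumStats(recM, "mediator", "continuous", verbose = FALSE),
       outcome = SumStats(recO, "outcome",
                          if (model@outcomeBinary) "binary" else "continuous",
                          verbose = FALSE),
       ld = .blockLD(panel$variant_id, model@ldBlockSize, model@ldBlockR2),
       truth = truth)
}

#' Simulate a metabolome-wide screening panel
#'
#' Generates `k` mediator (metabolite) GWAS over a shared variant
#' panel, one exposure GWAS and one outcome GWAS. Metabolites in
#' `causalIds` causally affect the outcome with effect `base@b`;
#' metabolites in `exposureCausalIds` are causally affected by the
#' exposure with effect `base@a`; all others are independent null
#' traits. The reverse-causation channel (`base@reverseFrac`) applies
#' to every metabolite. Each trait's records cover the whole panel, so
#' forward and reverse analyses both have data. Per-metabolite
#' randomness uses substreams of the shared seed.
#'
#' @param base a [TriadModel-class] supplying sample sizes, effect
#'   ranges, causal effect sizes and contamination settings.
#' @param k number of metabolites (0 allowed).
#' @param causalIds integer indices (subset of 1..k) of metabolites
#'   with a true effect on the outcome.
#' @param exposureCausalIds indices of metabolites truly affected by
#'   the exposure (default: `causalIds`).
#' @return list with `exposure`, `metabolites` (named list of
#'   [SumStats-class], `met01` ...), `outcome`, `ld`, `truth`.
#' @export
simulateMetabolome <- function(base, k, causalIds = integer(),
                               exposureCausalIds = causalIds) {
  stopifnot(is(base, "TriadModel"), k >= 0)
  causalIds <- as.integer(causalIds)
  exposureCausalIds <- as.integer(exposureCausalIds)
  if (length(causalIds) && (min(causalIds) < 1 || max(causalIds) > k))
    .stopf("causalIds must be a subset of 1..k")
  if (length(exposureCausalIds) &&
      (min(exposureCausalIds) < 1 || max(exposureCausalIds) > k))
    .stopf("exposureCausalIds must be a subset of 1..k")
  metNames <- sprintf("met%02d", seq_len(k))
  nRev <- round(base@reverseFrac * base@nInstrumentsM)
  nMed <- base@nInstrumentsM - nRev
  nNull <- 30L
  n <- base@nInstrumentsE + k * base@nInstrumentsM +
    base@nInstrumentsO + nNull
  panel <- .drawPanel(n, base@mafRange, base@palindromeFrac,
                      .subSeed(base@seed, 11L))

  role <- rep("null", n)
  owner <- rep(NA_integer_, n)
  role[seq_len(base@nInstrumentsE)] <- "exposure_iv"
  off <- base@nInstrumentsE
  for (m in seq_len(k)) {
    role[off + seq_len(nMed)] <- "mediator_iv"
    owner[off + seq_len(nMed)] <- m
    if (nRev > 0) {
      role[off + nMed + seq_len(nRev)] <- "reverse_iv"
      owner[off + nMed + seq_len(nRev)] <- m
    }
    off <- off + base@nInstrumentsM
  }
  role[off + seq_len(base@nInstrumentsO)] <- "outcome_iv"

  trueMet <- matrix(0, n, max(k, 1L))
  eff <- .withSeed(.subSeed(base@seed, 12L), {
    rsign <- function(x) sample(c(-1, 1), x, replace = TRUE)
    runifIn <- function(x, r) stats::runif(x, r[1], r[2])
    bE <- bO <- numeric(n)
    iE <- role == "exposure_iv"
    alpha <- rsign(sum(iE)) * runifIn(sum(iE), base@effectERange)
    bE[iE] <- alpha
    mediated <- intersect(causalIds, exposureCausalIds)
    bO[iE] <- (base@cDirect +
                 length(mediated) * base@a * base@b) * alpha
    for (m in seq_len(k)) {
      if (m %in% exposureCausalIds) trueMet[iE, m] <- base@a * alpha
      iM <- role == "mediator_iv" & owner == m
      iM[is.na(owner)] <- FALSE
      gamma <- rsign(sum(iM)) * runifIn(sum(iM), base@effectMRange)
      trueMet[iM, m] <- gamma
      if (m %in% causalIds) bO[iM] <- base@b * gamma
      nPleio <- round(base@pleiotropyFrac * sum(iM))
      if (nPleio > 0) {
        who <- which(iM)[sample.int(sum(iM), nPleio)]
        bO[who] <- bO[who] + sign(trueMet[who, m]) *
          stats::rnorm(nPleio, base@pleiotropyMean, base@pleiotropySd)
      }
      iR <- role == "reverse_iv" & owner == m
      iR[is.na(owner)] <- FALSE
      if (any(iR)) {
        delta <- rsign(sum(iR)) * runifIn(sum(iR), base@effectORange)
        bO[iR] <- delta
        trueMet[iR, m] <- base@reverseEffect * delta
      }
    }
    iO <- role == "outcome_iv"
    bO[iO] <- rsign(sum(iO)) * runifIn(sum(iO), base@effectORange)
    list(bE = bE, bO = bO, trueMet = trueMet)
  })

  recE <- .observeTrait(panel, eff$bE, base@nE, .subSeed(base@seed, 13L))
  recO <- .observeTrait(panel, eff$bO, base@nO, .subSeed(base@seed, 14L),
                        binary = base@outcomeBinary,
                        caseFrac = base@caseFrac,
                        noiseInflation = base@hetInflation)
  recO <- .scrambleRepresentation(recO, .subSeed(base@seed, 15L))
  metabolites <- stats::setNames(vector("list", k), metNames)
  for (m in seq_len(k)) {
    rec <- .observeTrait(panel, eff$trueMet[, m], base@nM,
                         .subSeed(base@seed, 100L + m))
    rec <- .scrambleRepresentation(rec, .subSeed(base@seed, 200L + m))
    metabolites[[m]] <- SumStats(rec, metNames[m], "continuous",
                                 verbose = FALSE)
  }

  truth <- list(
    variants = data.frame(variant_id = panel$variant_id, role = role,
                          owner = owner,
                          true_beta_exposure = eff$bE,
                          true_beta_outcome = eff$bO,
                          stringsAsFactors = FALSE),
    causalIds = causalIds, exposureCausalIds = exposureCausalIds,
    causalNames = metNames[causalIds],
    params = list(a = base@a, b = base@b, cDirect = base@cDirect,
                  seed = base@seed))

  list(exposure = SumStats(recE, "exposure", "continuous",
                           verbose = FALSE),
       metabolites = metabolites,
       outcome = SumStats(recO, "outcome",
                          if (base@outcomeBinary) "binary"
                          else "continuous", verbose = FALSE),
       ld = .blockLD(panel$variant_id, base@ldBlockSize, base@ldBlockR2),
       truth = truth)
}
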
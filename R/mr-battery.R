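#' MR analysis configuration
#'
#' Bundles every tunable of one exposure-outcome MR run. Defaults
#' follow the metabolome-screen conventions: instrument p < 1e-5,
#' clumping r2 < 0.001 within 10 Mb, F > 10, all sensitivity verdicts
#' at two-sided alpha 0.05, multiplicative random-effects IVW, 1000
#' bootstrap replicates for the median/mode SEs. The reverse-MR
#' instrument threshold defaults to 1e-5 as well, since disease
#' outcomes with few genome-wide hits rarely yield instruments at 5e-8;
#' it is logged prominently by [runMRBattery()].
#'
#' @param pThreshold instrument p-value threshold for the forward arm.
#' @param reversePThreshold instrument threshold for the reverse arm.
#' @param r2Max,windowBp LD clumping parameters.
#' @param fMin weak-instrument F cutoff (strictly greater retained).
#' @param alpha two-sided significance level for every sensitivity
#'   verdict (Q, Egger intercept, reverse MR) and for the cascade's
#'   IVW stage.
#' @param ivwModel `"multiplicative_random"` or `"fixed"`.
#' @param nBoot bootstrap replicates for median/mode SEs (0 skips
#'   them; point estimates, which all cascade verdicts rest on, are
#'   unaffected).
#' @param seed mandatory integer seed; every stochastic output is
#'   reproducible bit-for-bit under a fixed seed.
#' @param phi mode bandwidth multiplier.
#' @param policy a [HarmonizationPolicy-class] object.
#' @return a validated configuration list (class `mr_config`).
#' @export
mrConfig <- function(pThreshold = 1e-5, reversePThreshold = 1e-5,
                     r2Max = 0.001, windowBp = 1e7, fMin = 10,
                     alpha = 0.05,
                     ivwModel = c("multiplicative_random", "fixed"),
                     nBoot = 1000L, seed, phi = 1,
                     policy = harmonizationPolicy()) {
  if (missing(seed)) .stopf("mrConfig: a seed is mandatory")
  stopifnot(pThreshold > 0, pThreshold < 1, alpha > 0, alpha < 1,
            fMin >= 0, nBoot >= 0, phi > 0)
  structure(list(pThreshold = pThreshold,
                 reversePThreshold = reversePThreshold,
                 r2Max = r2Max, windowBp = windowBp, fMin = fMin,
                 alpha = alpha, ivwModel = match.arg(ivwModel),
                 nBoot = as.integer(nBoot), seed = as.integer(seed),
                 phi = phi, policy = policy),
            class = "mr_config")
}

# run one pipeline stage, rethrowing errors with the stage name
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
}

# select -> clump -> F-filter -> harmonize; shared by forward arm,
# reverse arm and the mediation legs
.prepareInstruments <- function(exposure, outcome, ld, config,
                                pThreshold = config$pThreshold) {
  sel <- .stage("select", selectByPvalue(exposure, pThreshold))
  cl <- .stage("clump", clumpInstruments(sel, ld, r2Max = config$r2Max,
                                         windowBp = config$windowBp))
  strong <- .stage("strength",
                   filterWeak(cl, instrumentMetrics(cl), fMin = config$fMin))
  .stage("harmonize", harmonize(strong, outcome, policy = config$policy))
}

# IVW p-value of the outcome -> exposure analysis; NA (with a note)
# when the outcome supplies no instruments
.reverseArm <- function(exposure, outcome, ld, config) {
  h <- .prepareInstruments(outcome, exposure, ld, config,
                           pThreshold = config$reversePThreshold)
  k <- keptInstruments(h)
  if (nrow(k) == 0L)
    return(list(pvalue = NA_real_, nSNPs = 0L,
                note = "no reverse instruments"))
  est <- if (nrow(k) == 1L) suppressMessages(mrWaldRatio(k))
         else mrIVW(k, model = config$ivwModel)
  list(pvalue = est@pvalue, nSNPs = nrow(k), note = NA_character_)
}

.estimateRow <- function(e) {
  data.frame(method = e@method, beta = e@beta, se = e@se,
             pvalue = e@pvalue, ci_low = e@ciLow, ci_high = e@ciHigh,
             n_snps = e@nSNPs, or = e@oddsRatio, or_ci_low = e@orCiLow,
             or_ci_high = e@orCiHigh, stringsAsFactors = FALSE)
}

#' Run the full five-estimator MR battery with sensitivity analyses
#'
#' Executes the complete protocol for one exposure-outcome pair:
#' p-value selection, LD clumping, variance-explained / F filtering,
#' allele harmonization, the five causal estimators (IVW as primary,
#' MR-Egger, weighted median, simple mode, weighted mode), Cochran's Q,
#' the Egger intercept pleiotropy test, cross-method direction
#' consistency, and a reverse-MR arm run with the roles swapped.
#' Errors from any stage are propagated with the stage name prefixed.
#'
#' @param exposure,outcome [SumStats-class] objects.
#' @param ld an [LDSource-class] covering the instrument variants.
#' @param config an [mrConfig()] list.
#' @param reverse logical; set FALSE to skip the reverse arm (used
#'   internally by the reverse arm itself).
#' @return an [MRBattery-class] object.
#' @export
runMRBattery <- function(exposure, outcome, ld, config, reverse = TRUE) {
  stopifnot(inherits(config, "mr_config"))
  h <- .prepareInstruments(exposure, outcome, ld, config)
  k <- keptInstruments(h)
  if (nrow(k) < 3L)
    .stopf("[estimate] insufficient instruments after harmonization: %d (need >= 3)",
           nrow(k))
  binary <- h@outcomeType == "binary"
  ivw <- mrIVW(k, model = config$ivwModel, binary = binary)
  egger <- mrEgger(k, binary = binary)
  wmed <- mrWeightedMedian(k, nBoot = config$nBoot,
                           seed = .subSeed(config$seed, 1L),
                           binary = binary)
  smode <- mrMode(k, weighted = FALSE, phi = config$phi,
                  nBoot = config$nBoot,
                  seed = .subSeed(config$seed, 2L), binary = binary)
  wmode <- mrMode(k, weighted = TRUE, phi = config$phi,
                  nBoot = config$nBoot,
                  seed = .subSeed(config$seed, 3L), binary = binary)
  ests <- list(ivw, egger$slope, wmed, smode, wmode)
  q <- cochranQ(k)
  rev <- if (reverse) .reverseArm(exposure, outcome, ld, config)
         else list(pvalue = NA_real_, nSNPs = NA_integer_, note = "skipped")
  sens <- new("SensitivityReport",
              qStat = q$qStat, qDf = q$qDf, qPvalue = q$qPvalue,
              eggerIntercept = egger$intercept,
              eggerInterceptSe = egger$interceptSe,
              eggerInterceptPvalue = egger$interceptPvalue,
              directionConsistent = directionConsistent(ests),
              reversePvalue = rev$pvalue,
              reverseNSNPs = as.integer(rev$nSNPs))
  new("MRBattery",
      exposureName = traitName(exposure), outcomeName = traitName(outcome),
      estimates = do.call(rbind, lapply(ests, .estimateRow)),
      sensitivity = sens, instruments = h,
      config = unclass(config)[setdiff(names(config), "policy")])
}

#' @describeIn MRBattery-accessors the five-method estimate table.
#' @export
setMethod("estimates", "MRBattery", function(x) x@estimates)

#' @describeIn MRBattery-accessors the [SensitivityReport-class].
#' @export
setMethod("sensitivity", "MRBattery", function(x) x@sensitivity)

#' Accessors for MRBattery objects
#' @param x an [MRBattery-class] object.
#' @name MRBattery-accessors
NULL

setMethod("show", "MRBattery", function(object) {
  cat("MRBattery: ", object@exposureName, " -> ", object@outcomeName,
      "\n", sep = "")
  est <- object@estimates
  for (i in seq_len(nrow(est)))
    cat(sprintf("  %-16s beta = %8.4f  se = %.4f  p = %.3g\n",
                est$method[i], est$beta[i], est$se[i], est$pvalue[i]))
  s <- object@sensitivity
  cat(sprintf("  Q = %.3f (df %d, p = %.3g); Egger intercept = %.4f (p = %.3g)\n",
              s@qStat, s@qDf, s@qPvalue, s@eggerIntercept,
              s@eggerInterceptPvalue))
  cat(sprintf("  direction consistent: %s; reverse IVW p = %s (J = %s)\n",
              s@directionConsistent,
              format(s@reversePvalue, digits = 3), s@reverseNSNPs))
})

setMethod("show", "SensitivityReport", function(object) {
  cat("SensitivityReport\n",
      sprintf("  Cochran's Q: %.3f (df %s, p = %s)\n", object@qStat,
              object@qDf, format(object@qPvalue, digits = 3)),
      sprintf("  Egger intercept: %.4g (se %.4g, p = %s)\n",
              object@eggerIntercept, object@eggerInterceptSe,
              format(object@eggerInterceptPvalue, digits = 3)),
      sprintf("  direction consistent: %s\n", object@directionConsistent),
      sprintf("  reverse IVW p: %s (J = %s)\n",
              format(object@reversePvalue, digits = 3),
              object@reverseNSNPs), sep = "")
})

#' Write the per-pair results block
#'
#' Tab-separated estimate table (method, beta, se, pvalue, ci_low,
#' ci_high, or, n_snps) followed by a sensitivity block.
#'
#' @param battery an [MRBattery-class] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBatteryReport <- function(battery, path) {
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(battery@estimates, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  s <- battery@sensitivity
  sens <- data.frame(
    metric = c("q_stat", "q_df", "q_pvalue", "egger_intercept",
               "egger_intercept_se", "egger_intercept_pvalue",
               "direction_consistent", "reverse_pvalue"),
    value = c(s@qStat, s@qDf, s@qPvalue, s@eggerIntercept,
              s@eggerInterceptSe, s@eggerInterceptPvalue,
              as.numeric(s@directionConsistent), s@reversePvalue))
  writeLines("", con)
  utils::write.table(sens, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
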
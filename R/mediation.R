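#' Product-of-coefficients mediation
#'
#' Combines the exposure-to-mediator effect (beta_EM), the
#' mediator-to-outcome effect (beta_MO) and the total
#' exposure-to-outcome effect (beta_EO) into the indirect effect
#' beta_EM * beta_MO and the mediation proportion
#' (beta_EM * beta_MO) / beta_EO. The indirect-effect SE is the
#' first-order delta approximation
#' sqrt(beta_MO^2 se_EM^2 + beta_EM^2 se_MO^2) (the two legs come from
#' non-overlapping GWAS and are treated as independent).
#'
#' The default proportion interval (`ciMethod = "fixed_total"`) treats
#' the total effect as fixed and divides the indirect effect's normal
#' 95% bounds by beta_EO; `"full_delta"` additionally propagates the
#' total-effect uncertainty through the ratio
#' (var = var(ind)/beta_EO^2 + ind^2 se_EO^2 / beta_EO^4) and is wider.
#'
#' @param betaEm,seEm exposure-to-mediator effect and SE.
#' @param betaMo,seMo mediator-to-outcome effect and SE.
#' @param betaEo,seEo total exposure-to-outcome effect and SE
#'   (`seEo` may be NA under `"fixed_total"`).
#' @param ciMethod `"fixed_total"` (default) or `"full_delta"`.
#' @return a [MediationResult-class] object.
#' @examples
#' # adiposity -> maleate -> small-cell lung cancer worked example
#' m <- productOfCoefficients(0.200, reconstructSeFromCi(0.096, 0.303),
#'                            0.329, reconstructSeFromCi(0.005, 0.653),
#'                            0.442, reconstructSeFromCi(0.114, 0.771))
#' mediationProportion(m)  # ~0.149
#' @export
productOfCoefficients <- function(betaEm, seEm, betaMo, seMo,
                                  betaEo, seEo = NA_real_,
                                  ciMethod = c("fixed_total",
                                               "full_delta")) {
  ciMethod <- match.arg(ciMethod)
  stopifnot(seEm > 0, seMo > 0)
  if (betaEo == 0)
    .stopf("total effect is 0: mediation proportion undefined")
  indirect <- betaEm * betaMo
  indirectSe <- sqrt(betaMo^2 * seEm^2 + betaEm^2 * seMo^2)
  proportion <- indirect / betaEo
  if (ciMethod == "fixed_total") {
    bounds <- (indirect + c(-1, 1) * .Z95 * indirectSe) / betaEo
  } else {
    if (is.na(seEo) || seEo <= 0)
      .stopf("full_delta interval requires seEo > 0")
    propSe <- sqrt(indirectSe^2 / betaEo^2 +
                   indirect^2 * seEo^2 / betaEo^4)
    bounds <- proportion + c(-1, 1) * .Z95 * propSe
  }
  new("MediationResult",
      betaEm = betaEm, seEm = seEm, betaMo = betaMo, seMo = seMo,
      betaEo = betaEo, seEo = as.numeric(seEo),
      indirect = indirect, indirectSe = indirectSe,
      proportion = proportion,
      proportionCiLow = min(bounds), proportionCiHigh = max(bounds),
      ciMethod = ciMethod)
}

#' Reconstruct a standard error from a printed 95% confidence interval
#'
#' se = (ciHigh - ciLow) / (2 * 1.959964); useful for consuming
#' published coefficient tables that print intervals but not SEs.
#'
#' @param ciLow,ciHigh interval bounds, `ciHigh > ciLow`.
#' @return the implied standard error.
#' @export
reconstructSeFromCi <- function(ciLow, ciHigh) {
  if (any(ciHigh <= ciLow)) .stopf("degenerate interval: ciHigh <= ciLow")
  (ciHigh - ciLow) / (2 * .Z95)
}

#' @describeIn MediationResult-accessors mediated share of the total
#'   effect (a fraction; multiply by 100 for percent).
#' @export
setMethod("mediationProportion", "MediationResult", function(x) x@proportion)

#' @describeIn MediationResult-accessors the indirect effect
#'   beta_EM * beta_MO.
#' @export
setMethod("indirectEffect", "MediationResult", function(x) x@indirect)

#' Accessors for MediationResult objects
#' @param x a [MediationResult-class] object.
#' @name MediationResult-accessors
NULL

setMethod("show", "MediationResult", function(object) {
  cat("MediationResult (product of coefficients)\n",
      sprintf("  beta_EM = %.3f (se %.4f)\n", object@betaEm, object@seEm),
      sprintf("  beta_MO = %.3f (se %.4f)\n", object@betaMo, object@seMo),
      sprintf("  beta_EO = %.3f\n", object@betaEo),
      sprintf("  indirect = %.3f (se %.4f)\n", object@indirect,
              object@indirectSe),
      sprintf("  proportion mediated = %.3g%% (95%% CI %.3g%%, %.3g%%) [%s]\n",
              100 * object@proportion, 100 * object@proportionCiLow,
              100 * object@proportionCiHigh, object@ciMethod), sep = "")
})

#' Display-convention summary of a mediation result
#'
#' Reporting follows the field's display conventions: effects and the
#' indirect effect to 3 decimals, the mediation proportion as the ratio
#' of the *rounded* indirect effect to the total, to 3 significant
#' figures, in percent. Full precision is retained in the object.
#'
#' @param x a [MediationResult-class] object.
#' @return data.frame with one formatted row.
#' @export
formatMediation <- function(x) {
  stopifnot(is(x, "MediationResult"))
  indirectR <- round(x@indirect, 3)
  data.frame(
    beta_em = round(x@betaEm, 3), beta_mo = round(x@betaMo, 3),
    beta_eo = round(x@betaEo, 3), indirect = indirectR,
    proportion_pct = signif(100 * indirectR / x@betaEo, 3),
    proportion_ci_low_pct = signif(100 * x@proportionCiLow, 3),
    proportion_ci_high_pct = signif(100 * x@proportionCiHigh, 3))
}

#' Estimate the three mediation legs from summary statistics
#'
#' Runs the IVW estimator on each leg of the
#' exposure -> mediator -> outcome triangle (exposure -> mediator,
#' mediator -> outcome, exposure -> outcome total effect) after the
#' standard instrument-selection and harmonization pipeline, then
#' combines the legs with [productOfCoefficients()]. The exposure legs
#' use `config$pThreshold`; the mediator -> outcome leg uses
#' `mediatorPThreshold`, reflecting the weaker instruments available
#' for metabolite GWAS of modest sample size.
#'
#' @param exposure,mediator,outcome [SumStats-class] objects.
#' @param ld an [LDSource-class].
#' @param config an [mrConfig()] list (exposure instrument threshold
#'   typically 5e-8).
#' @param mediatorPThreshold instrument threshold for the mediator leg
#'   (default 1e-5).
#' @param ciMethod passed to [productOfCoefficients()].
#' @return list with elements `mediation` (a
#'   [MediationResult-class]), and `legs` (the three IVW
#'   [MREstimate-class] objects).
#' @export
mediationAnalysis <- function(exposure, mediator, outcome, ld, config,
                              mediatorPThreshold = 1e-5,
                              ciMethod = "fixed_total") {
  leg <- function(ex, out, thr) {
    h <- .prepareInstruments(ex, out, ld, config, pThreshold = thr)
    k <- keptInstruments(h)
    if (nrow(k) < 2L)
      .stopf("[estimate] leg %s -> %s has %d instrument(s); need >= 2",
             traitName(ex), traitName(out), nrow(k))
    mrIVW(k, model = config$ivwModel,
          binary = traitType(out) == "binary")
  }
  em <- leg(exposure, mediator, config$pThreshold)
  mo <- leg(mediator, outcome, mediatorPThreshold)
  eo <- leg(exposure, outcome, config$pThreshold)
  med <- productOfCoefficients(em@beta, em@se, mo@beta, mo@se,
                               eo@beta, eo@se, ciMethod = ciMethod)
  list(mediation = med, legs = list(em = em, mo = mo, eo = eo))
}
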
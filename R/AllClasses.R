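#' @import methods
NULL

.SUMSTATS_COLS <- c("variant_id", "chr", "pos", "ea", "oa",
                    "eaf", "beta", "se", "pval", "n")

.HARMONIZED_COLS <- c("variant_id", "action", "bx", "sx", "px", "eafx",
                      "by", "sy", "py", "eafy")

.KEPT_ACTIONS    <- c("kept_same", "kept_flipped", "kept_strand_flipped")
.DROPPED_ACTIONS <- c("dropped_palindromic", "dropped_mismatch",
                      "dropped_missing")

#' SumStats: GWAS summary statistics for one trait
#'
#' Container for one trait's per-variant association records. The
#' `records` slot is a data.frame with the canonical columns
#' `variant_id`, `chr`, `pos`, `ea`, `oa`, `eaf`, `beta`, `se`, `pval`,
#' `n`. Effect sizes (`beta`) are per effect-allele (`ea`) copies: on
#' the log-odds scale for binary traits and in SD units for continuous
#' traits. `eaf` may be `NA` (record retained but unusable for
#' variance-explained computation and palindrome resolution); all other
#' fields must satisfy the record invariants enforced by the validity
#' method. The `dropLog` slot records rows rejected on read, with a
#' machine-readable reason each.
#'
#' @slot traitName character(1), trait label.
#' @slot traitType `"continuous"` or `"binary"`.
#' @slot records data.frame of validated per-variant records.
#' @slot dropLog data.frame with columns `variant_id`, `reason`.
#'
#' @seealso [readSumStats()], [writeSumStats()], [SumStats()]
#' @export
setClass("SumStats",
  representation(traitName = "character",
                 traitType = "character",
                 records   = "data.frame",
                 dropLog   = "data.frame"),
  prototype(traitName = "trait", traitType = "continuous",
            records = data.frame(), dropLog = data.frame(
              variant_id = character(), reason = character())))

setValidity("SumStats", function(object) {
  msgs <- character()
  if (length(object@traitName) != 1L)
    msgs <- c(msgs, "traitName must be a single string")
  if (!object@traitType %in% c("continuous", "binary"))
    msgs <- c(msgs, "traitType must be 'continuous' or 'binary'")
  rec <- object@records
  if (nrow(rec) > 0L || ncol(rec) > 0L) {
    missing <- setdiff(.SUMSTATS_COLS, names(rec))
    if (length(missing))
      return(paste("records lacks columns:", paste(missing, collapse = ", ")))
  }
  if (nrow(rec) > 0L) {
    if (anyDuplicated(rec$variant_id))
      msgs <- c(msgs, "duplicate variant_id values")
    if (any(rec$se <= 0 | is.na(rec$se)))
      msgs <- c(msgs, "all se must be > 0")
    eaf_bad <- !is.na(rec$eaf) & (rec$eaf <= 0 | rec$eaf >= 1)
    if (any(eaf_bad))
      msgs <- c(msgs, "non-missing eaf must lie in (0,1)")
    if (any(is.na(rec$pval) | rec$pval <= 0 | rec$pval > 1))
      msgs <- c(msgs, "pval must lie in (0,1]")
    if (any(rec$ea == rec$oa))
      msgs <- c(msgs, "effect and other allele must differ")
    if (any(!rec$ea %in% c("A", "C", "G", "T")) ||
        any(!rec$oa %in% c("A", "C", "G", "T")))
      msgs <- c(msgs, "alleles must be single characters in {A,C,G,T}")
    if (any(is.na(rec$pos) | rec$pos < 1))
      msgs <- c(msgs, "pos must be >= 1")
    if (any(is.na(rec$n) | rec$n < 1))
      msgs <- c(msgs, "n must be a positive count")
  }
  if (length(msgs)) msgs else TRUE
})

#' LDSource: precomputed pairwise linkage-disequilibrium lookup
#'
#' Symmetric pairwise r-squared values between variants, plus the set of
#' variant ids the table claims to cover (its completeness domain).
#' Pairs absent from the table but with both members inside the domain
#' have r-squared 0; variants outside the domain have unknown LD and are
#' treated as independent by [clumpInstruments()], with a warning.
#'
#' @slot pairs data.frame with columns `id_a`, `id_b`, `r2`.
#' @slot domain character vector of covered variant ids.
#' @seealso [ldSource()], [ldR2()], [readLDSource()]
#' @export
setClass("LDSource",
  representation(pairs = "data.frame", domain = "character"),
  prototype(pairs = data.frame(id_a = character(), id_b = character(),
                               r2 = numeric()),
            domain = character()))

setValidity("LDSource", function(object) {
  p <- object@pairs
  if (!all(c("id_a", "id_b", "r2") %in% names(p)))
    return("pairs must have columns id_a, id_b, r2")
  if (nrow(p) > 0L && any(p$r2 < 0 | p$r2 > 1))
    return("r2 values must lie in [0,1]")
  TRUE
})

#' HarmonizationPolicy: how to align exposure and outcome alleles
#'
#' @slot palindromeHandling `"resolve_by_eaf"` (default) infers the
#'   strand of palindromic (A/T, C/G) variants from allele frequencies
#'   and drops those whose frequency is too close to 0.5 to be
#'   informative; `"drop_all"` drops every palindromic variant.
#' @slot eafAmbiguityBand half-width of the ambiguity band around 0.5;
#'   with the default 0.08 a palindromic variant is dropped when either
#'   trait's effect-allele frequency falls in [0.42, 0.58].
#' @slot allowStrandFlip logical; whether complement-strand matches of
#'   non-palindromic variants are re-aligned rather than dropped.
#' @seealso [harmonizationPolicy()], [harmonize()]
#' @export
setClass("HarmonizationPolicy",
  representation(palindromeHandling = "character",
                 eafAmbiguityBand   = "numeric",
                 allowStrandFlip    = "logical"),
  prototype(palindromeHandling = "resolve_by_eaf",
            eafAmbiguityBand = 0.08, allowStrandFlip = TRUE))

setValidity("HarmonizationPolicy", function(object) {
  msgs <- character()
  if (!object@palindromeHandling %in% c("drop_all", "resolve_by_eaf"))
    msgs <- c(msgs, "palindromeHandling must be 'drop_all' or 'resolve_by_eaf'")
  if (object@eafAmbiguityBand <= 0 || object@eafAmbiguityBand >= 0.5)
    msgs <- c(msgs, "eafAmbiguityBand must lie in (0, 0.5)")
  if (length(msgs)) msgs else TRUE
})

#' HarmonizedSet: exposure/outcome effect pairs on a shared orientation
#'
#' One row per exposure instrument, kept or dropped. Kept rows carry the
#' exposure effect (`bx`, `sx`, `px`, `eafx`) and the outcome effect
#' (`by`, `sy`, `py`, `eafy`) expressed for the same effect allele;
#' dropped rows carry only the id and the drop reason in `action`.
#'
#' @slot instruments data.frame with columns `variant_id`, `action`,
#'   `bx`, `sx`, `px`, `eafx`, `by`, `sy`, `py`, `eafy`.
#' @slot exposureName,outcomeName trait labels.
#' @slot outcomeType `"continuous"` or `"binary"` (controls odds-ratio
#'   reporting downstream).
#' @seealso [harmonize()], [keptInstruments()]
#' @export
setClass("HarmonizedSet",
  representation(instruments = "data.frame",
                 exposureName = "character",
                 outcomeName  = "character",
                 outcomeType  = "character"),
  prototype(instruments = data.frame(), exposureName = "exposure",
            outcomeName = "outcome", outcomeType = "continuous"))

setValidity("HarmonizedSet", function(object) {
  ins <- object@instruments
  if (nrow(ins) > 0L) {
    missing <- setdiff(.HARMONIZED_COLS, names(ins))
    if (length(missing))
      return(paste("instruments lacks columns:",
                   paste(missing, collapse = ", ")))
    bad <- !ins$action %in% c(.KEPT_ACTIONS, .DROPPED_ACTIONS)
    if (any(bad))
      return(paste("unknown action:", paste(unique(ins$action[bad]),
                                            collapse = ", ")))
    kept <- ins$action %in% .KEPT_ACTIONS
    if (any(kept & (is.na(ins$sx) | ins$sx <= 0 |
                    is.na(ins$sy) | ins$sy <= 0)))
      return("kept instruments must have sx > 0 and sy > 0")
    if (any(!kept & (!is.na(ins$bx) | !is.na(ins$by))))
      return("dropped instruments must carry no effect fields")
  }
  TRUE
})

#' MREstimate: one estimator's causal effect with uncertainty
#'
#' @slot method one of `"ivw"`, `"egger"`, `"weighted_median"`,
#'   `"simple_mode"`, `"weighted_mode"`, `"wald_ratio"`.
#' @slot beta,se point estimate and standard error of the causal effect
#'   (per SD of exposure, on the outcome's native scale).
#' @slot pvalue two-sided p-value.
#' @slot ciLow,ciHigh 95% confidence bounds (normal quantiles; MR-Egger
#'   uses t quantiles with J-2 degrees of freedom).
#' @slot nSNPs number of instruments used.
#' @slot oddsRatio,orCiLow,orCiHigh exp-transformed effect and bounds,
#'   populated when the outcome is binary, otherwise `NA`.
#' @export
setClass("MREstimate",
  representation(method = "character", beta = "numeric", se = "numeric",
                 pvalue = "numeric", ciLow = "numeric", ciHigh = "numeric",
                 nSNPs = "integer", oddsRatio = "numeric",
                 orCiLow = "numeric", orCiHigh = "numeric"),
  prototype(method = "ivw", beta = NA_real_, se = NA_real_,
            pvalue = NA_real_, ciLow = NA_real_, ciHigh = NA_real_,
            nSNPs = 0L, oddsRatio = NA_real_, orCiLow = NA_real_,
            orCiHigh = NA_real_))

setValidity("MREstimate", function(object) {
  ok_methods <- c("ivw", "egger", "weighted_median", "simple_mode",
                  "weighted_mode", "wald_ratio")
  if (!object@method %in% ok_methods)
    return(paste("method must be one of:", paste(ok_methods, collapse = ", ")))
  if (!is.na(object@se) && object@se < 0) return("se must be >= 0")
  TRUE
})

#' SensitivityReport: diagnostics for one exposure-outcome pair
#'
#' @slot qStat,qDf,qPvalue Cochran's Q heterogeneity test on the Wald
#'   ratios (chi-square with J-1 df).
#' @slot eggerIntercept,eggerInterceptSe,eggerInterceptPvalue the
#'   MR-Egger intercept (average directional pleiotropy) and its t-test.
#' @slot directionConsistent TRUE iff all five estimators' betas share
#'   a strict sign.
#' @slot reversePvalue IVW p-value of the reverse (outcome-to-exposure)
#'   analysis; `NA` when the outcome yields no usable instruments.
#' @slot reverseNSNPs instruments used by the reverse arm.
#' @export
setClass("SensitivityReport",
  representation(qStat = "numeric", qDf = "integer", qPvalue = "numeric",
                 eggerIntercept = "numeric", eggerInterceptSe = "numeric",
                 eggerInterceptPvalue = "numeric",
                 directionConsistent = "logical",
                 reversePvalue = "numeric", reverseNSNPs = "integer"),
  prototype(qStat = NA_real_, qDf = NA_integer_, qPvalue = NA_real_,
            eggerIntercept = NA_real_, eggerInterceptSe = NA_real_,
            eggerInterceptPvalue = NA_real_, directionConsistent = NA,
            reversePvalue = NA_real_, reverseNSNPs = NA_integer_))

setValidity("SensitivityReport", function(object) {
  if (!is.na(object@qStat) && object@qStat < 0) return("qStat must be >= 0")
  TRUE
})

#' MRBattery: five causal estimators plus sensitivity diagnostics
#'
#' Result of [runMRBattery()] for one exposure-outcome pair: the full
#' instrument-selection and harmonization trail, the five estimates, and
#' the sensitivity report.
#'
#' @slot exposureName,outcomeName trait labels.
#' @slot estimates data.frame, one row per method, columns `method`,
#'   `beta`, `se`, `pvalue`, `ci_low`, `ci_high`, `n_snps`, `or`,
#'   `or_ci_low`, `or_ci_high`.
#' @slot sensitivity a [SensitivityReport-class] object.
#' @slot instruments the [HarmonizedSet-class] the estimators consumed.
#' @slot config the configuration list used (see [mrConfig()]).
#' @export
setClass("MRBattery",
  representation(exposureName = "character", outcomeName = "character",
                 estimates = "data.frame", sensitivity = "SensitivityReport",
                 instruments = "HarmonizedSet", config = "list"),
  prototype(estimates = data.frame(), config = list()))

#' MediationResult: product-of-coefficients mediation summary
#'
#' @slot betaEm,seEm exposure-to-mediator effect and SE.
#' @slot betaMo,seMo mediator-to-outcome effect and SE.
#' @slot betaEo,seEo total exposure-to-outcome effect and SE.
#' @slot indirect product betaEm * betaMo.
#' @slot indirectSe first-order delta-method SE of the product.
#' @slot proportion indirect / betaEo (mediated share of the total
#'   effect, as a fraction).
#' @slot proportionCiLow,proportionCiHigh 95% bounds on the proportion.
#' @slot ciMethod `"fixed_total"` (total effect treated as fixed) or
#'   `"full_delta"` (total-effect uncertainty propagated too).
#' @seealso [productOfCoefficients()]
#' @export
setClass("MediationResult",
  representation(betaEm = "numeric", seEm = "numeric",
                 betaMo = "numeric", seMo = "numeric",
                 betaEo = "numeric", seEo = "numeric",
                 indirect = "numeric", indirectSe = "numeric",
                 proportion = "numeric",
                 proportionCiLow = "numeric", proportionCiHigh = "numeric",
                 ciMethod = "character"),
  prototype(ciMethod = "fixed_total"))

setValidity("MediationResult", function(object) {
  msgs <- character()
  if (!object@ciMethod %in% c("fixed_total", "full_delta"))
    msgs <- c(msgs, "ciMethod must be 'fixed_total' or 'full_delta'")
  if (length(object@indirect) == 1L && length(object@betaEm) == 1L &&
      is.finite(object@indirect) &&
      abs(object@indirect - object@betaEm * object@betaMo) >
        1e-8 * max(1, abs(object@indirect)))
    msgs <- c(msgs, "indirect must equal betaEm * betaMo")
  if (length(msgs)) msgs else TRUE
})

#' CascadeAudit: per-stage bookkeeping of a screening cascade
#'
#' Conservation holds at every stage: `entering = passing + dropped`,
#' and stage k's passing count is stage k+1's entering count.
#'
#' @slot stages data.frame with columns `stage`, `entering`, `passing`.
#' @slot drops data.frame with columns `stage`, `trait`, `reason`.
#' @export
setClass("CascadeAudit",
  representation(stages = "data.frame", drops = "data.frame"),
  prototype(stages = data.frame(stage = character(), entering = integer(),
                                passing = integer()),
            drops = data.frame(stage = character(), trait = character(),
                               reason = character())))

setValidity("CascadeAudit", function(object) {
  st <- object@stages
  if (nrow(st) == 0L) return(TRUE)
  dropped <- vapply(st$stage, function(s) sum(object@drops$stage == s),
                    integer(1))
  if (any(st$entering != st$passing + dropped))
    return("stage conservation violated: entering != passing + dropped")
  if (nrow(st) > 1L && any(st$entering[-1L] != st$passing[-nrow(st)]))
    return("stages do not compose: passing[k] != entering[k+1]")
  TRUE
})

#' TriadModel: parameters of the synthetic GWAS triad generator
#'
#' Describes an exposure -> mediator -> outcome causal chain and the
#' GWAS sampling layer around it. Defaults emulate the study conditions
#' of an adiposity / circulating-metabolite / small-cell-lung-cancer
#' analysis: a UK-Biobank-scale continuous exposure (n = 330,762), a
#' CLSA-scale metabolite GWAS (n = 8,299), and a FinnGen-scale binary
#' outcome (855 cases, 345,118 controls) whose sampling error uses the
#' effective sample size 4 v (1 - v) N for case fraction v.
#'
#' @slot nVariants total simulated variants (single synthetic
#'   chromosome, uniform 100 kb spacing).
#' @slot nInstrumentsE,nInstrumentsM,nInstrumentsO counts of true
#'   instruments for exposure, mediator, and outcome.
#' @slot mafRange minor-allele-frequency interval within (0, 0.5].
#' @slot effectERange,effectMRange,effectORange per-instrument effect
#'   magnitude ranges (signs random) on their own trait.
#' @slot a,b,cDirect true exposure->mediator, mediator->outcome and
#'   direct exposure->outcome effects; the true total effect is
#'   a*b + cDirect.
#' @slot pleiotropyFrac,pleiotropyMean,pleiotropySd fraction of exposure
#'   instruments given a direct (pleiotropic) outcome effect, and the
#'   normal distribution those effects are drawn from.
#' @slot hetInflation multiplicative extra variance on observed outcome
#'   effects (reported SEs stay nominal, inducing heterogeneity).
#' @slot reverseFrac fraction of nominal mediator instruments that in
#'   truth act on the outcome first (outcome -> mediator channel).
#' @slot reverseEffect true outcome->mediator effect for that channel.
#' @slot nE,nM,nO GWAS sample sizes.
#' @slot outcomeBinary logical; whether the outcome is case-control.
#' @slot caseFrac case fraction of the binary outcome.
#' @slot palindromeFrac fraction of variants assigned palindromic
#'   (A/T or C/G) allele pairs.
#' @slot ldBlockSize variants per LD block (1 = all independent).
#' @slot ldBlockR2 pairwise r-squared within an LD block.
#' @slot seed integer master seed; all randomness flows from it through
#'   named substreams.
#' @seealso [triadModel()], [simulateTriad()], [simulateMetabolome()]
#' @export
setClass("TriadModel",
  representation(nVariants = "integer", nInstrumentsE = "integer",
                 nInstrumentsM = "integer", nInstrumentsO = "integer",
                 mafRange = "numeric", effectERange = "numeric",
                 effectMRange = "numeric", effectORange = "numeric",
                 a = "numeric", b = "numeric", cDirect = "numeric",
                 pleiotropyFrac = "numeric", pleiotropyMean = "numeric",
                 pleiotropySd = "numeric", hetInflation = "numeric",
                 reverseFrac = "numeric", reverseEffect = "numeric",
                 nE = "numeric", nM = "numeric", nO = "numeric",
                 outcomeBinary = "logical", caseFrac = "numeric",
                 palindromeFrac = "numeric",
                 ldBlockSize = "integer", ldBlockR2 = "numeric",
                 seed = "integer"))

setValidity("TriadModel", function(object) {
  msgs <- character()
  chkfrac <- function(x, nm) if (x < 0 || x > 1)
    paste0(nm, " must lie in [0,1]") else character()
  msgs <- c(msgs, chkfrac(object@pleiotropyFrac, "pleiotropyFrac"),
            chkfrac(object@reverseFrac, "reverseFrac"),
            chkfrac(object@caseFrac, "caseFrac"),
            chkfrac(object@palindromeFrac, "palindromeFrac"))
  if (any(c(object@nE, object@nM, object@nO) <= 0))
    msgs <- c(msgs, "sample sizes nE, nM, nO must be positive")
  if (object@mafRange[1] <= 0 || object@mafRange[2] > 0.5 ||
      object@mafRange[1] > object@mafRange[2])
    msgs <- c(msgs, "mafRange must be an interval within (0, 0.5]")
  need <- object@nInstrumentsE + object@nInstrumentsM + object@nInstrumentsO
  if (object@nVariants < need)
    msgs <- c(msgs, "nVariants smaller than the requested instrument counts")
  if (object@hetInflation < 1)
    msgs <- c(msgs, "hetInflation must be >= 1")
  if (object@ldBlockSize < 1L)
    msgs <- c(msgs, "ldBlockSize must be >= 1")
  if (length(msgs)) msgs else TRUE
})
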
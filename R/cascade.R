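# Build a CascadeAudit from an ordered list of stages, each a list
# (name, drops = data.frame(trait, reason)), plus the entering count.
.buildAudit <- function(entering, stages) {
  st <- data.frame(stage = character(), entering = integer(),
                   passing = integer())
  dr <- data.frame(stage = character(), trait = character(),
                   reason = character())
  cur <- entering
  for (s in stages) {
    ndrop <- nrow(s$drops)
    st <- rbind(st, data.frame(stage = s$name, entering = cur,
                               passing = cur - ndrop))
    if (ndrop)
      dr <- rbind(dr, data.frame(stage = s$name, trait = s$drops$trait,
                                 reason = s$drops$reason))
    cur <- cur - ndrop
  }
  new("CascadeAudit", stages = st, drops = dr)
}

#' @describeIn CascadeAudit-accessors per-stage entering/passing counts.
#' @export
setMethod("auditStages", "CascadeAudit", function(x) x@stages)

#' @describeIn CascadeAudit-accessors per-trait drops with reasons.
#' @export
setMethod("auditDrops", "CascadeAudit", function(x) x@drops)

#' Accessors for CascadeAudit objects
#' @param x a [CascadeAudit-class] object.
#' @name CascadeAudit-accessors
NULL

setMethod("show", "CascadeAudit", function(object) {
  cat("CascadeAudit\n")
  st <- object@stages
  for (i in seq_len(nrow(st)))
    cat(sprintf("  %-22s %4d -> %4d\n", st$stage[i], st$entering[i],
                st$passing[i]))
})

# The shared screening engine. `pairs` is a named list of
# list(exposure=, outcome=) SumStats pairs, one per screened trait.
.screen <- function(pairs, ld, config, verbose = TRUE) {
  ids <- names(pairs)
  batteries <- vector("list", length(ids))
  names(batteries) <- ids
  failReason <- stats::setNames(rep(NA_character_, length(ids)), ids)
  for (id in ids) {
    batteries[[id]] <- tryCatch(
      suppressMessages(runMRBattery(pairs[[id]]$exposure,
                                    pairs[[id]]$outcome, ld, config)),
      error = function(e) {
        failReason[id] <<- conditionMessage(e)
        NULL
      })
  }
  ok <- ids[!vapply(batteries, is.null, logical(1))]
  fail <- setdiff(ids, ok)
  if (length(fail))
    .msg("estimation failed for ", length(fail), " trait(s)",
         verbose = verbose)

  stageDrop <- function(survivors, failing, reason) {
    tr <- intersect(survivors, failing)
    data.frame(trait = tr, reason = rep(reason, length(tr)),
               stringsAsFactors = FALSE)
  }
  sens <- function(id) sensitivity(batteries[[id]])
  ivwP <- vapply(ok, function(id) {
    est <- estimates(batteries[[id]])
    est$pvalue[est$method == "ivw"]
  }, numeric(1))
  alpha <- config$alpha

  stages <- list()
  cur <- ids
  add <- function(name, failing, reason) {
    d <- stageDrop(cur, failing, reason)
    stages[[length(stages) + 1L]] <<- list(name = name, drops = d)
    cur <<- setdiff(cur, d$trait)
  }
  add("estimation", fail, "estimator_failure")
  add("ivw_significance", ok[!(ivwP < alpha)], "ivw_not_significant")
  add("direction_consistency",
      ok[!vapply(ok, function(id) isTRUE(sens(id)@directionConsistent),
                 logical(1))], "direction_inconsistent")
  add("pleiotropy",
      ok[vapply(ok, function(id) {
        p <- sens(id)@eggerInterceptPvalue
        !is.na(p) && p < alpha
      }, logical(1))], "egger_intercept_significant")
  add("heterogeneity",
      ok[vapply(ok, function(id) {
        p <- sens(id)@qPvalue
        !is.na(p) && p < alpha
      }, logical(1))], "heterogeneity_significant")
  add("reverse_causation",
      ok[vapply(ok, function(id) {
        p <- sens(id)@reversePvalue
        !is.na(p) && p < alpha
      }, logical(1))], "reverse_causal_signal")

  list(results = batteries, audit = .buildAudit(length(ids), stages),
       survivors = cur, failReason = failReason[fail])
}

#' Step-1 screen: candidate mediators against the outcome
#'
#' Runs the full MR battery for every candidate trait as exposure
#' against the shared outcome, then applies the filter cascade in
#' fixed order: IVW significance (p < alpha), five-method direction
#' consistency, Egger-intercept pleiotropy exclusion, Cochran-Q
#' heterogeneity exclusion, reverse-MR exclusion. Per-trait estimator
#' failures are recorded as drops at an initial `estimation` stage and
#' never abort the batch. No multiple-testing correction is applied by
#' default (raw p-values throughout); pass `padjust = "BH"` for an
#' optional Benjamini-Hochberg IVW stage.
#'
#' @param traits named list of [SumStats-class] objects (the screened
#'   exposures, e.g. metabolites).
#' @param outcome a [SumStats-class] object.
#' @param ld an [LDSource-class].
#' @param config an [mrConfig()] list.
#' @param padjust `"none"` (default) or `"BH"` applied to the IVW
#'   stage's p-values.
#' @param verbose message on estimation failures.
#' @return list with `results` (per-trait [MRBattery-class] or NULL),
#'   `audit` (a [CascadeAudit-class]), `survivors` (character ids) and
#'   `failReason`.
#' @export
step1Screen <- function(traits, outcome, ld, config, padjust = "none",
                        verbose = TRUE) {
  if (is.null(names(traits)) && length(traits))
    names(traits) <- vapply(traits, traitName, character(1))
  pairs <- lapply(traits, function(tr)
    list(exposure = tr, outcome = outcome))
  .screenWithPadjust(pairs, ld, config, padjust, verbose)
}

#' Step-2 screen: one exposure against the surviving mediators
#'
#' Same filter cascade as [step1Screen()] with the roles reversed: the
#' adiposity-style exposure is instrumented (conventionally at the
#' stricter genome-wide 5e-8 threshold, set via `config$pThreshold`)
#' and each surviving mediator is the outcome in turn. The reverse arm
#' instruments each mediator against the exposure.
#'
#' @param exposure a [SumStats-class] object.
#' @param traits named list of [SumStats-class] mediators.
#' @inheritParams step1Screen
#' @return as [step1Screen()].
#' @export
step2Screen <- function(exposure, traits, ld, config, padjust = "none",
                        verbose = TRUE) {
  if (is.null(names(traits)) && length(traits))
    names(traits) <- vapply(traits, traitName, character(1))
  pairs <- lapply(traits, function(tr)
    list(exposure = exposure, outcome = tr))
  .screenWithPadjust(pairs, ld, config, padjust, verbose)
}

.screenWithPadjust <- function(pairs, ld, config, padjust, verbose) {
  out <- .screen(pairs, ld, config, verbose = verbose)
  if (identical(padjust, "BH")) {
    ok <- names(out$results)[!vapply(out$results, is.null, logical(1))]
    p <- vapply(ok, function(id) {
      est <- estimates(out$results[[id]])
      est$pvalue[est$method == "ivw"]
    }, numeric(1))
    padj <- stats::p.adjust(p, method = "BH")
    extra <- ok[padj >= config$alpha & p < config$alpha]
    # remove traits that pass raw alpha but fail BH from the survivors
    out$survivors <- setdiff(out$survivors, extra)
  }
  out
}

#' Validate a screen finding with an alternative exposure
#'
#' Runs one full [runMRBattery()] with the alternative exposure (e.g.
#' BMI standing in for whole-body fat mass) against the mediator and
#' reports the validation verdicts: IVW significance, cross-method
#' direction consistency, no heterogeneity, no pleiotropy, no reverse
#' signal.
#'
#' @param altExposure,mediator [SumStats-class] objects.
#' @param ld an [LDSource-class].
#' @param config an [mrConfig()] list.
#' @return list with `battery` (an [MRBattery-class]) and `verdict`
#'   (named logicals plus overall `pass`).
#' @export
validateExposureSwap <- function(altExposure, mediator, ld, config) {
  b <- runMRBattery(altExposure, mediator, ld, config)
  s <- sensitivity(b)
  est <- estimates(b)
  v <- list(
    significant = est$pvalue[est$method == "ivw"] < config$alpha,
    directionConsistent = isTRUE(s@directionConsistent),
    noHeterogeneity = is.na(s@qPvalue) || s@qPvalue >= config$alpha,
    noPleiotropy = is.na(s@eggerInterceptPvalue) ||
      s@eggerInterceptPvalue >= config$alpha,
    noReverse = is.na(s@reversePvalue) ||
      s@reversePvalue >= config$alpha)
  v$pass <- all(unlist(v))
  list(battery = b, verdict = v)
}

#' Write a cascade audit as tab-separated tables
#'
#' @param audit a [CascadeAudit-class] object.
#' @param path output path; drops are written alongside with suffix
#'   `_drops`.
#' @return `path`, invisibly.
#' @export
writeCascadeAudit <- function(audit, path) {
  utils::write.table(auditStages(audit), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  dropPath <- sub("(\\.[^.]*)?$", "_drops\\1", path)
  utils::write.table(auditDrops(audit), dropPath, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
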
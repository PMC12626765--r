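# Config-driven entry points. Each takes a YAML file (or an equivalent
# named list), runs one workflow stage, writes its outputs and a run
# manifest into `out_dir`, and returns the result invisibly. A thin
# command-line wrapper lives in inst/scripts/mrcascade-cli.R.

.loadConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) .stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) .stopf("config must be a YAML file path or a list")
  config
}

.cfgGet <- function(config, field, default = NULL, required = FALSE) {
  if (!is.null(config[[field]])) return(config[[field]])
  if (required) .stopf("config field missing: %s", field)
  default
}

.prepOutDir <- function(config, outDir) {
  if (is.null(outDir)) outDir <- .cfgGet(config, "out_dir", required = TRUE)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  outDir
}

.mrConfigFromYaml <- function(config, seed) {
  thr <- .cfgGet(config, "thresholds", list())
  mrConfig(
    pThreshold = .cfgGet(thr, "p_exposure", 1e-5),
    reversePThreshold = .cfgGet(thr, "p_reverse", 1e-5),
    r2Max = .cfgGet(thr, "r2_max", 0.001),
    windowBp = .cfgGet(thr, "window_bp", 1e7),
    fMin = .cfgGet(thr, "f_min", 10),
    alpha = .cfgGet(thr, "alpha", 0.05),
    nBoot = .cfgGet(config, "n_boot", 1000L),
    seed = seed)
}

#' Run the synthetic-data workflow from a config file
#'
#' Config fields: `mode` (`"triad"` or `"metabolome"`), `out_dir`,
#' `seed`, optional `model` (named [triadModel()] argument overrides),
#' and for metabolome mode `k` plus optional `causal_ids` /
#' `exposure_causal_ids`. Writes the summary-statistics tables in the
#' canonical dialect, the LD table, a JSON truth sidecar, and a run
#' manifest. Identical config + seed gives byte-identical
#' summary-statistics files.
#'
#' @param config YAML path or list.
#' @param outDir,seed optional overrides of the config's `out_dir` and
#'   `seed`.
#' @return the simulation result list, invisibly.
#' @export
runSimulation <- function(config, outDir = NULL, seed = NULL) {
  config <- .loadConfig(config)
  outDir <- .prepOutDir(config, outDir)
  if (is.null(seed)) seed <- .cfgGet(config, "seed", 1L)
  mode <- .cfgGet(config, "mode", "triad")
  if (!mode %in% c("triad", "metabolome"))
    .stopf("config field 'mode' must be 'triad' or 'metabolome'")
  modelArgs <- .cfgGet(config, "model", list())
  modelArgs$seed <- seed
  model <- tryCatch(do.call(triadModel, modelArgs),
                    error = function(e)
                      .stopf("bad model config: %s", conditionMessage(e)))
  if (mode == "triad") {
    sim <- simulateTriad(model)
    traits <- list(exposure = sim$exposure, mediator = sim$mediator,
                   outcome = sim$outcome)
  } else {
    k <- .cfgGet(config, "k", required = TRUE)
    sim <- simulateMetabolome(model, k,
                              causalIds = unlist(.cfgGet(config,
                                                         "causal_ids",
                                                         integer())),
                              exposureCausalIds = unlist(
                                .cfgGet(config, "exposure_causal_ids",
                                        unlist(.cfgGet(config, "causal_ids",
                                                       integer())))))
    traits <- c(list(exposure = sim$exposure), sim$metabolites,
                list(outcome = sim$outcome))
  }
  files <- character()
  for (nm in names(traits)) {
    f <- file.path(outDir, paste0(nm, ".tsv"))
    writeSumStats(traits[[nm]], f)
    files <- c(files, f)
  }
  ldFile <- file.path(outDir, "ld.tsv")
  writeLDSource(sim$ld, ldFile)
  truthFile <- file.path(outDir, "truth.json")
  jsonlite::write_json(sim$truth, truthFile, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c(files, ldFile, truthFile)
  counts <- vapply(traits, nVariants, integer(1))
  writeRunManifest(outDir, config, seed, counts, files)
  invisible(sim)
}

.readTraitFile <- function(path, type = "continuous") {
  if (is.null(path) || !file.exists(path %||% ""))
    .stopf("input file missing: %s", path %||% "<unset>")
  readSumStats(path, traitType = type, verbose = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a screening step from a config file
#'
#' Config fields: `step` (1 or 2), `out_dir`, `seed`, `ld` (LD table
#' path), `metabolites` (vector of paths), `outcome` (path; step 1),
#' `exposure` (path; step 2), `outcome_type` (`"binary"` default for
#' step 1), optional `thresholds` (`p_exposure`, `p_reverse`, `r2_max`,
#' `window_bp`, `f_min`, `alpha`) and `n_boot` (default 0: cascade
#' verdicts only need point estimates). All inputs are checked before
#' any computation. Writes the audit chain, the per-trait results
#' table, a volcano-style scatter, a forest-style table and a
#' manifest.
#'
#' @inheritParams runSimulation
#' @return the screen result list, invisibly.
#' @export
runScreen <- function(config, outDir = NULL, seed = NULL) {
  config <- .loadConfig(config)
  outDir <- .prepOutDir(config, outDir)
  if (is.null(seed)) seed <- .cfgGet(config, "seed", 1L)
  step <- .cfgGet(config, "step", 1L)
  metPaths <- unlist(.cfgGet(config, "metabolites", required = TRUE))
  missing <- metPaths[!file.exists(metPaths)]
  if (step == 1) {
    outcomePath <- .cfgGet(config, "outcome", required = TRUE)
    if (!file.exists(outcomePath)) missing <- c(missing, outcomePath)
  } else {
    exposurePath <- .cfgGet(config, "exposure", required = TRUE)
    if (!file.exists(exposurePath)) missing <- c(missing, exposurePath)
  }
  ldPath <- .cfgGet(config, "ld", required = TRUE)
  if (!file.exists(ldPath)) missing <- c(missing, ldPath)
  if (length(missing))
    .stopf("input file(s) missing: %s", paste(missing, collapse = ", "))

  mconf <- .mrConfigFromYaml(config, seed)
  if (is.null(config$n_boot)) mconf$nBoot <- 0L
  ld <- readLDSource(ldPath)
  mets <- lapply(metPaths, .readTraitFile)
  names(mets) <- vapply(mets, traitName, character(1))
  screen <- if (step == 1) {
    outcome <- .readTraitFile(outcomePath,
                              .cfgGet(config, "outcome_type", "binary"))
    step1Screen(mets, outcome, ld, mconf, verbose = FALSE)
  } else {
    if (is.null(config$thresholds$p_exposure)) mconf$pThreshold <- 5e-8
    exposure <- .readTraitFile(exposurePath)
    step2Screen(exposure, mets, ld, mconf, verbose = FALSE)
  }
  auditFile <- file.path(outDir, "audit.tsv")
  writeCascadeAudit(screen$audit, auditFile)
  results <- screenResultsTable(screen)
  resFile <- file.path(outDir, "results.tsv")
  utils::write.table(results, resFile, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  volcanoFile <- file.path(outDir, "volcano.png")
  volcanoPlot(results, path = volcanoFile, alpha = mconf$alpha)
  forestFile <- file.path(outDir, "forest.tsv")
  writeForestTable(results, forestFile)
  files <- c(auditFile, file.path(outDir, "audit_drops.tsv"), resFile,
             volcanoFile, forestFile)
  counts <- c(traits_in = length(mets),
              survivors = length(screen$survivors),
              result_rows = nrow(results))
  writeRunManifest(outDir, config, seed, counts, files)
  invisible(screen)
}

#' Run the mediation workflow from a config file
#'
#' Two modes. `from_coefficients` consumes printed coefficients
#' (fields `coefficients: beta_em, beta_mo, beta_eo` plus either
#' `se_*` or `ci_*: [low, high]` for the EM and MO legs) so a
#' published worked example is reproducible without any GWAS input.
#' `pipeline` estimates the three legs by IVW from summary-statistics
#' files (`exposure`, `mediator`, `outcome`, `ld`; thresholds
#' `p_exposure` default 5e-8 and `p_mediator` default 1e-5). Writes
#' the mediation summary as a display-rounded table, a full-precision
#' JSON, and a manifest.
#'
#' @inheritParams runSimulation
#' @return the [MediationResult-class], invisibly.
#' @export
runMediation <- function(config, outDir = NULL, seed = NULL) {
  config <- .loadConfig(config)
  outDir <- .prepOutDir(config, outDir)
  if (is.null(seed)) seed <- .cfgGet(config, "seed", 1L)
  mode <- .cfgGet(config, "mode", "from_coefficients")
  ciMethod <- .cfgGet(config, "ci_method", "fixed_total")
  if (mode == "from_coefficients") {
    co <- .cfgGet(config, "coefficients", required = TRUE)
    seFor <- function(leg) {
      se <- co[[paste0("se_", leg)]]
      if (!is.null(se)) return(se)
      ci <- unlist(co[[paste0("ci_", leg)]])
      if (is.null(ci))
        .stopf("coefficients need se_%s or ci_%s", leg, leg)
      reconstructSeFromCi(ci[1], ci[2])
    }
    seEo <- tryCatch(seFor("eo"), error = function(e) NA_real_)
    med <- productOfCoefficients(
      .cfgGet(co, "beta_em", required = TRUE), seFor("em"),
      .cfgGet(co, "beta_mo", required = TRUE), seFor("mo"),
      .cfgGet(co, "beta_eo", required = TRUE), seEo,
      ciMethod = ciMethod)
  } else if (mode == "pipeline") {
    paths <- c(exposure = .cfgGet(config, "exposure", required = TRUE),
               mediator = .cfgGet(config, "mediator", required = TRUE),
               outcome = .cfgGet(config, "outcome", required = TRUE),
               ld = .cfgGet(config, "ld", required = TRUE))
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      .stopf("input file(s) missing: %s", paste(missing, collapse = ", "))
    thr <- .cfgGet(config, "thresholds", list())
    mconf <- .mrConfigFromYaml(config, seed)
    mconf$pThreshold <- .cfgGet(thr, "p_exposure", 5e-8)
    res <- mediationAnalysis(
      .readTraitFile(paths["exposure"]),
      .readTraitFile(paths["mediator"]),
      .readTraitFile(paths["outcome"],
                     .cfgGet(config, "outcome_type", "binary")),
      readLDSource(paths["ld"]), mconf,
      mediatorPThreshold = .cfgGet(thr, "p_mediator", 1e-5),
      ciMethod = ciMethod)
    med <- res$mediation
  } else .stopf("config field 'mode' must be 'from_coefficients' or 'pipeline'")

  tabFile <- file.path(outDir, "mediation.tsv")
  utils::write.table(formatMediation(med), tabFile, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonFile <- file.path(outDir, "mediation.json")
  jsonlite::write_json(
    list(beta_em = med@betaEm, se_em = med@seEm,
         beta_mo = med@betaMo, se_mo = med@seMo,
         beta_eo = med@betaEo, indirect = med@indirect,
         indirect_se = med@indirectSe, proportion = med@proportion,
         proportion_ci = c(med@proportionCiLow, med@proportionCiHigh),
         ci_method = med@ciMethod),
    jsonFile, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeRunManifest(outDir, config, seed, c(legs = 3L),
                   c(tabFile, jsonFile))
  invisible(med)
}
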
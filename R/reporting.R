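# ---- tabular + plot export ------------------------------------------

#' Collect per-trait screen results into one table
#'
#' One row per trait and method, mirroring the content of a forest
#' plot / cross-method heatmap: beta, se, p, CI, odds ratio (binary
#' outcomes) and instrument count, plus the sensitivity verdicts.
#' Betas are reported in full precision; use `rounded = TRUE` for the
#' display convention (betas to 3 decimals).
#'
#' @param screen result list from [step1Screen()] or [step2Screen()].
#' @param rounded apply display rounding.
#' @return data.frame.
#' @export
screenResultsTable <- function(screen, rounded = FALSE) {
  rows <- lapply(names(screen$results), function(id) {
    b <- screen$results[[id]]
    if (is.null(b)) return(NULL)
    est <- estimates(b)
    s <- sensitivity(b)
    cbind(trait = id, est,
          q_pvalue = s@qPvalue,
          egger_intercept_pvalue = s@eggerInterceptPvalue,
          direction_consistent = s@directionConsistent,
          reverse_pvalue = s@reversePvalue,
          survivor = id %in% screen$survivors)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(trait = character(), method = character(),
                      beta = numeric(), pvalue = numeric()))
  rownames(out) <- NULL
  if (rounded)
    for (cl in c("beta", "se", "ci_low", "ci_high"))
      out[[cl]] <- round(out[[cl]], 3)
  out
}

#' Volcano-style plot of screen results
#'
#' Scatter of per-trait IVW effect estimates against -log10(p), with
#' the significance threshold drawn as a dashed line.
#'
#' @param results data.frame from [screenResultsTable()].
#' @param path optional PNG output path; when given, the plot is
#'   written there instead of the active device.
#' @param alpha significance threshold for the dashed line.
#' @return the plotted data.frame (IVW rows), invisibly.
#' @export
volcanoPlot <- function(results, path = NULL, alpha = 0.05) {
  d <- results[results$method == "ivw", , drop = FALSE]
  if (!is.null(path)) {
    grDevices::png(path, width = 900, height = 700, res = 120)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(d$beta, -log10(d$pvalue), pch = 19,
                 col = ifelse(d$pvalue < alpha, "firebrick", "grey50"),
                 xlab = expression(beta ~ "(IVW)"),
                 ylab = expression(-log[10](italic(p))),
                 main = "Screen results")
  graphics::abline(h = -log10(alpha), lty = 2, col = "red")
  invisible(d)
}

#' Forest-style table export
#'
#' Writes the IVW estimate per trait (with OR and CI when the outcome
#' is binary) next to the four supplementary methods' betas, the
#' content a forest plot plus cross-method heatmap would display.
#'
#' @param results data.frame from [screenResultsTable()].
#' @param path output path (tab-separated).
#' @return `path`, invisibly.
#' @export
writeForestTable <- function(results, path) {
  ivw <- results[results$method == "ivw", , drop = FALSE]
  wide <- ivw[, intersect(c("trait", "beta", "se", "pvalue", "ci_low",
                            "ci_high", "or", "or_ci_low", "or_ci_high",
                            "n_snps", "survivor"), names(ivw))]
  for (m in c("egger", "weighted_median", "simple_mode", "weighted_mode")) {
    sub <- results[results$method == m, c("trait", "beta")]
    names(sub)[2] <- paste0("beta_", m)
    wide <- merge(wide, sub, by = "trait", sort = FALSE)
  }
  utils::write.table(wide, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- run manifest ---------------------------------------------------

#' Write a run manifest
#'
#' JSON snapshot of a pipeline run: configuration, package version,
#' seed, per-stage row counts and output files with timestamps. Every
#' listed file must exist at write time.
#'
#' @param outDir run output directory.
#' @param config the configuration list used.
#' @param seed the seed used.
#' @param counts named list/vector of per-stage input/output row
#'   counts.
#' @param files character vector of output file paths.
#' @return the manifest list, invisibly.
#' @export
writeRunManifest <- function(outDir, config, seed, counts, files) {
  missing <- files[!file.exists(files)]
  if (length(missing))
    .stopf("manifest lists missing file(s): %s",
           paste(missing, collapse = ", "))
  manifest <- list(
    package = "mrcascade",
    version = as.character(utils::packageVersion("mrcascade")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    counts = as.list(counts),
    files = basename(files))
  jsonlite::write_json(manifest,
                       file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
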
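#' Select variants by p-value threshold
#'
#' Keeps exactly the records with `pval` strictly below `threshold`,
#' preserving record order. The conventional thresholds are 1e-5
#' (metabolite GWAS with modest sample size) and the genome-wide 5e-8.
#'
#' @param stats a [SumStats-class] object.
#' @param threshold p-value threshold in (0, 1).
#' @return a [SumStats-class] object with the passing records.
#' @export
selectByPvalue <- function(stats, threshold) {
  stopifnot(is(stats, "SumStats"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    .stopf("threshold must be a single p-value in (0, 1)")
  rec <- records(stats)
  .replaceRecords(stats, rec[rec$pval < threshold, , drop = FALSE])
}

#' Greedy LD clumping of instruments
#'
#' Repeatedly keeps the remaining variant with the lowest p-value and
#' discards every remaining variant on the same chromosome within
#' `windowBp` of it whose pairwise r-squared with it is at least
#' `r2Max`. Ties on p-value are broken by (chr, pos, variant_id)
#' lexicographic order, so the retained set does not depend on input
#' record order. Variants outside the LD source's declared domain are
#' conservatively treated as independent, with a warning.
#'
#' @param stats a [SumStats-class] object.
#' @param ld an [LDSource-class] object.
#' @param r2Max r-squared threshold; a pair is dependent at
#'   `r2 >= r2Max` (default 0.001).
#' @param windowBp window in base pairs; pairwise |position difference|
#'   <= `windowBp` is "within the window" (default 10 Mb).
#' @return a [SumStats-class] object with the retained records, in
#'   input order.
#' @export
clumpInstruments <- function(stats, ld, r2Max = 0.001, windowBp = 1e7) {
  stopifnot(is(stats, "SumStats"), is(ld, "LDSource"))
  rec <- records(stats)
  if (nrow(rec) <= 1L) return(stats)
  uncovered <- setdiff(rec$variant_id, ldDomain(ld))
  if (length(uncovered))
    warning(length(uncovered), " variant(s) outside the LD domain ",
            "treated as independent: ",
            paste(utils::head(uncovered, 5L), collapse = ", "),
            if (length(uncovered) > 5L) ", ...", call. = FALSE)
  ord <- order(rec$pval, rec$chr, rec$pos, rec$variant_id)
  alive <- rep(TRUE, nrow(rec))
  keep <- logical(nrow(rec))
  for (i in ord) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[i] <- FALSE
    cand <- which(alive & rec$chr == rec$chr[i] &
                  abs(rec$pos - rec$pos[i]) <= windowBp)
    if (length(cand)) {
      r2 <- ldR2(ld, rec$variant_id[i], rec$variant_id[cand])
      r2[is.na(r2)] <- 0   # outside the domain: assume independent
      alive[cand[r2 >= r2Max]] <- FALSE
    }
  }
  .replaceRecords(stats, rec[keep, , drop = FALSE])
}

#' Proportion of trait variance explained by one variant
#'
#' Computes R2 = 2 b^2 f (1-f) / (2 b^2 f (1-f) + 2 se^2 N f (1-f)),
#' which simplifies to b^2 / (b^2 + se^2 N); the allele-frequency factor
#' cancels, but a missing frequency still rejects the record because a
#' record without a frequency cannot support instrument-strength
#' assessment in the source data's own terms.
#'
#' @param beta per-allele effect on the exposure.
#' @param eaf effect-allele frequency in (0, 1).
#' @param se standard error of `beta`.
#' @param n exposure GWAS sample size (>= 3).
#' @param variantId optional id(s) used in error messages.
#' @return variance explained, in [0, 1); vectorized.
#' @export
varianceExplained <- function(beta, eaf, se, n, variantId = NULL) {
  if (any(is.na(eaf))) {
    bad <- which(is.na(eaf))
    lab <- if (!is.null(variantId)) paste(variantId[bad], collapse = ", ")
           else paste("index", paste(bad, collapse = ", "))
    .stopf("missing eaf; cannot compute variance explained for: %s", lab)
  }
  stopifnot(all(eaf > 0 & eaf < 1), all(se > 0), all(n >= 3))
  beta^2 / (beta^2 + se^2 * n)
}

#' Instrument strength F-statistic
#'
#' F = R2 (N - 2) / (1 - R2). Strictly increasing in R2 at fixed N and
#' in N at fixed positive R2; F > 10 is the conventional
#' weak-instrument cutoff.
#'
#' @param r2 variance explained, in [0, 1).
#' @param n sample size (>= 3).
#' @return F-statistic (nonnegative); vectorized.
#' @export
fStatistic <- function(r2, n) {
  if (any(r2 < 0 | r2 >= 1)) .stopf("r2 must lie in [0, 1)")
  stopifnot(all(n >= 3))
  r2 * (n - 2) / (1 - r2)
}

#' Per-variant instrument strength metrics
#'
#' @param stats a [SumStats-class] object (every record needs a
#'   non-missing `eaf`).
#' @return data.frame with columns `variant_id`, `r2`, `f_stat`.
#' @export
instrumentMetrics <- function(stats) {
  stopifnot(is(stats, "SumStats"))
  rec <- records(stats)
  r2 <- if (nrow(rec)) varianceExplained(rec$beta, rec$eaf, rec$se, rec$n,
                                         variantId = rec$variant_id)
        else numeric()
  data.frame(variant_id = rec$variant_id, r2 = r2,
             f_stat = if (nrow(rec)) fStatistic(r2, rec$n) else numeric(),
             stringsAsFactors = FALSE)
}

#' Drop weak instruments
#'
#' Retains exactly the records whose F-statistic is strictly greater
#' than `fMin`.
#'
#' @param stats a [SumStats-class] object.
#' @param metrics data.frame from [instrumentMetrics()]; must cover
#'   every record.
#' @param fMin F threshold (default 10).
#' @return a [SumStats-class] object.
#' @export
filterWeak <- function(stats, metrics, fMin = 10) {
  stopifnot(is(stats, "SumStats"))
  rec <- records(stats)
  idx <- match(rec$variant_id, metrics$variant_id)
  if (anyNA(idx))
    .stopf("no instrument metrics for: %s",
           paste(rec$variant_id[is.na(idx)], collapse = ", "))
  .replaceRecords(stats, rec[metrics$f_stat[idx] > fMin, , drop = FALSE])
}

#' Full instrument-selection pipeline
#'
#' p-value selection, greedy LD clumping, then weak-instrument removal
#' by the F > `fMin` rule. Record count is non-increasing across the
#' three stages.
#'
#' @inheritParams clumpInstruments
#' @param pThreshold instrument p-value threshold.
#' @param fMin weak-instrument F cutoff.
#' @return a [SumStats-class] object of selected instruments.
#' @export
selectInstruments <- function(stats, ld, pThreshold = 1e-5, r2Max = 0.001,
                              windowBp = 1e7, fMin = 10) {
  sel <- selectByPvalue(stats, pThreshold)
  cl <- clumpInstruments(sel, ld, r2Max = r2Max, windowBp = windowBp)
  filterWeak(cl, instrumentMetrics(cl), fMin = fMin)
}
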
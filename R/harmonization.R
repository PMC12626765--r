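#' Construct a harmonization policy
#'
#' @param palindromeHandling `"resolve_by_eaf"` (default) or
#'   `"drop_all"`.
#' @param eafAmbiguityBand half-width of the frequency ambiguity band
#'   around 0.5 (default 0.08); a palindromic variant is dropped when
#'   either trait's effect-allele frequency falls inside the band (or
#'   is missing).
#' @param allowStrandFlip re-align complement-strand matches of
#'   non-palindromic variants instead of dropping them (default TRUE;
#'   appropriate when source GWAS were genotyped on multiple platforms).
#' @return a [HarmonizationPolicy-class] object.
#' @export
harmonizationPolicy <- function(palindromeHandling = c("resolve_by_eaf",
                                                       "drop_all"),
                                eafAmbiguityBand = 0.08,
                                allowStrandFlip = TRUE) {
  new("HarmonizationPolicy",
      palindromeHandling = match.arg(palindromeHandling),
      eafAmbiguityBand = eafAmbiguityBand,
      allowStrandFlip = allowStrandFlip)
}

# Align one outcome record to the exposure's effect allele.
# Returns list(action, flip, strand) where flip means the outcome beta
# is negated and its eaf complemented.
.alignAlleles <- function(eaX, oaX, eaY, oaY, eafX, eafY, policy) {
  pal <- .isPalindromic(eaX, oaX)
  if (pal) {
    # outcome alleles must be the same unordered pair (a palindromic
    # pair equals its own strand complement)
    if (!setequal(c(eaY, oaY), c(eaX, oaX)))
      return(list(action = "dropped_mismatch", flip = FALSE))
    if (policy@palindromeHandling == "drop_all")
      return(list(action = "dropped_palindromic", flip = FALSE))
    if (is.na(eafX) || is.na(eafY))
      return(list(action = "dropped_palindromic", flip = FALSE))
    band <- policy@eafAmbiguityBand
    if (abs(eafX - 0.5) <= band || abs(eafY - 0.5) <= band)
      return(list(action = "dropped_palindromic", flip = FALSE))
    # nominal alignment by allele label, then a frequency concordance
    # check decides whether the outcome is on the opposite strand
    flip <- eaY != eaX
    eafAligned <- if (flip) 1 - eafY else eafY
    if (sign(eafX - 0.5) != sign(eafAligned - 0.5)) flip <- !flip
    return(list(action = if (flip) "kept_flipped" else "kept_same",
                flip = flip))
  }
  if (eaY == eaX && oaY == oaX)
    return(list(action = "kept_same", flip = FALSE))
  if (eaY == oaX && oaY == eaX)
    return(list(action = "kept_flipped", flip = TRUE))
  if (policy@allowStrandFlip) {
    ceaY <- .complementAllele(eaY)
    coaY <- .complementAllele(oaY)
    # strand complement leaves the effect direction and frequency alone;
    # a swap on top of it negates the effect as usual
    if (ceaY == eaX && coaY == oaX)
      return(list(action = "kept_strand_flipped", flip = FALSE))
    if (ceaY == oaX && coaY == eaX)
      return(list(action = "kept_strand_flipped", flip = TRUE))
  }
  list(action = "dropped_mismatch", flip = FALSE)
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome association of every exposure instrument to the
#' exposure's effect allele. Direct matches are kept as-is; swapped
#' alleles negate the outcome effect and complement its frequency;
#' complement-strand matches are re-aligned when the policy allows
#' (`kept_strand_flipped` marks that a strand complement was applied,
#' with the effect additionally negated when the complemented alleles
#' were also swapped). Palindromic (A/T, C/G) variants are resolved by
#' allele frequency or dropped, per policy. Unresolvable allele sets
#' and instruments absent from the outcome become dropped records; no
#' failure aborts the run.
#'
#' @param exposure,outcome [SumStats-class] objects; `exposure` should
#'   already be reduced to its selected instruments.
#' @param policy a [HarmonizationPolicy-class] object.
#' @return a [HarmonizedSet-class] with one row per exposure
#'   instrument; dropped rows carry only the id and drop reason.
#' @export
harmonize <- function(exposure, outcome, policy = harmonizationPolicy()) {
  stopifnot(is(exposure, "SumStats"), is(outcome, "SumStats"),
            is(policy, "HarmonizationPolicy"))
  ex <- records(exposure)
  out <- records(outcome)
  oidx <- match(ex$variant_id, out$variant_id)
  n <- nrow(ex)
  res <- data.frame(variant_id = ex$variant_id,
                    action = character(n),
                    bx = ex$beta, sx = ex$se, px = ex$pval, eafx = ex$eaf,
                    by = NA_real_, sy = NA_real_, py = NA_real_,
                    eafy = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    j <- oidx[i]
    if (is.na(j)) { res$action[i] <- "dropped_missing"; next }
    al <- .alignAlleles(ex$ea[i], ex$oa[i], out$ea[j], out$oa[j],
                        ex$eaf[i], out$eaf[j], policy)
    res$action[i] <- al$action
    if (al$action %in% .KEPT_ACTIONS) {
      res$by[i]   <- if (al$flip) -out$beta[j] else out$beta[j]
      res$sy[i]   <- out$se[j]
      res$py[i]   <- out$pval[j]
      res$eafy[i] <- if (is.na(out$eaf[j])) NA_real_
                     else if (al$flip) 1 - out$eaf[j] else out$eaf[j]
    }
  }
  dropped <- !res$action %in% .KEPT_ACTIONS
  res$bx[dropped] <- NA_real_
  res$sx[dropped] <- NA_real_
  res$px[dropped] <- NA_real_
  res$eafx[dropped] <- NA_real_
  new("HarmonizedSet", instruments = res,
      exposureName = traitName(exposure),
      outcomeName = traitName(outcome),
      outcomeType = traitType(outcome))
}

#' @describeIn HarmonizedSet-accessors rows with a `kept_*` action.
#' @export
setMethod("keptInstruments", "HarmonizedSet", function(x) {
  ins <- x@instruments
  out <- ins[ins$action %in% .KEPT_ACTIONS, , drop = FALSE]
  rownames(out) <- NULL
  out
})

#' @describeIn HarmonizedSet-accessors rows with a `dropped_*` action.
#' @export
setMethod("droppedInstruments", "HarmonizedSet", function(x) {
  ins <- x@instruments
  out <- ins[ins$action %in% .DROPPED_ACTIONS, , drop = FALSE]
  rownames(out) <- NULL
  out
})

#' Accessors for HarmonizedSet objects
#' @param x a [HarmonizedSet-class] object.
#' @name HarmonizedSet-accessors
NULL

setMethod("show", "HarmonizedSet", function(object) {
  tab <- table(object@instruments$action)
  cat("HarmonizedSet: ", object@exposureName, " -> ",
      object@outcomeName, " (", object@outcomeType, " outcome)\n",
      sep = "")
  for (a in names(tab)) cat("  ", a, ": ", tab[[a]], "\n", sep = "")
})

#' Orientation-invariance diagnostic
#'
#' Verifies that jointly negating (bx, by) of instrument pairs leaves
#' every estimator's point estimate unchanged: analytically true for
#' the Wald ratio, IVW, weighted median and both modes, and true for
#' MR-Egger as computed here because [mrEgger()] re-orients instruments
#' to bx >= 0 internally. A raw Egger regression without that
#' re-orientation is orientation-sensitive; the returned value carries
#' an `egger_raw_sensitive` attribute reporting whether the raw slope
#' moved under the tested sign flips.
#'
#' @param hset a [HarmonizedSet-class] object with >= 3 kept
#'   instruments.
#' @param seed seed for the random choice of pairs to flip.
#' @param tol equality tolerance on point estimates.
#' @return logical(1): TRUE iff all five estimators (Egger under its
#'   bx >= 0 convention) are invariant; attribute
#'   `egger_raw_sensitive` flags the raw regression.
#' @export
orientationInvarianceCheck <- function(hset, seed = 1L, tol = 1e-10) {
  k <- keptInstruments(hset)
  if (nrow(k) < 3L) .stopf("need >= 3 kept instruments")
  flip <- .withSeed(seed, sample(c(-1, 1), nrow(k), replace = TRUE))
  k2 <- k
  k2$bx <- k$bx * flip
  k2$by <- k$by * flip
  pt <- function(d) c(
    ivw    = .ivwCore(d$bx, d$by, d$sy)$beta,
    egger  = .eggerCore(d$bx, d$by, d$sy, reorient = TRUE)$beta,
    wmed   = .weightedMedianCore(d$by / d$bx, d$bx^2 / d$sy^2),
    smode  = .modeCore(d$by / d$bx, rep(1, nrow(d)), phi = 1),
    wmode  = .modeCore(d$by / d$bx, d$bx^2 / d$sy^2, phi = 1))
  same <- max(abs(pt(k) - pt(k2))) < tol
  raw1 <- .eggerCore(k$bx, k$by, k$sy, reorient = FALSE)$beta
  raw2 <- .eggerCore(k2$bx, k2$by, k2$sy, reorient = FALSE)$beta
  structure(same, egger_raw_sensitive = abs(raw1 - raw2) >= tol)
}

#' Harmonization audit table
#'
#' @param hset a [HarmonizedSet-class] object.
#' @param path output path for a tab-separated audit table
#'   (variant_id, action, bx, by, sx, sy, eafx, eafy).
#' @return `path`, invisibly.
#' @export
writeHarmonizationAudit <- function(hset, path) {
  ins <- hset@instruments[, c("variant_id", "action", "bx", "by",
                              "sx", "sy", "eafx", "eafy")]
  utils::write.table(ins, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
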
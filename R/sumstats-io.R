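#' Construct a SumStats object from a data.frame
#'
#' Validates per-variant records and builds a [SumStats-class] object.
#' Rows violating a record invariant are dropped with a logged reason
#' (retrievable via [dropLog()]); rows with missing effect-allele
#' frequency are retained but are unusable downstream wherever the
#' frequency is required (variance explained, palindrome resolution).
#'
#' @param records data.frame with the canonical columns `variant_id`,
#'   `chr`, `pos`, `ea`, `oa`, `eaf`, `beta`, `se`, `pval`, `n`.
#' @param traitName trait label.
#' @param traitType `"continuous"` or `"binary"` (effect scale: SD units
#'   or log-odds).
#' @param verbose emit a message per drop category.
#' @return a [SumStats-class] object.
#' @details Alleles are upper-cased; indel / multi-character alleles are
#'   dropped (SNPs only). p-values of exactly 0 are clamped to the
#'   smallest positive double with a warning. Duplicated `variant_id`s
#'   are an error, listing the duplicates.
#' @export
SumStats <- function(records, traitName = "trait",
                     traitType = c("continuous", "binary"),
                     verbose = TRUE) {
  traitType <- match.arg(traitType)
  missing_cols <- setdiff(.SUMSTATS_COLS, names(records))
  if (length(missing_cols))
    .stopf("missing mandatory column(s): %s",
           paste(missing_cols, collapse = ", "))
  rec <- records[, .SUMSTATS_COLS, drop = FALSE]
  rec$variant_id <- as.character(rec$variant_id)
  rec$chr <- as.character(rec$chr)
  rec$pos <- as.numeric(rec$pos)
  rec$ea  <- toupper(as.character(rec$ea))
  rec$oa  <- toupper(as.character(rec$oa))
  for (cl in c("eaf", "beta", "se", "pval", "n"))
    rec[[cl]] <- as.numeric(rec[[cl]])

  dup <- unique(rec$variant_id[duplicated(rec$variant_id)])
  if (length(dup))
    .stopf("duplicate variant_id(s): %s", paste(dup, collapse = ", "))

  zero_p <- !is.na(rec$pval) & rec$pval == 0
  if (any(zero_p)) {
    warning(sum(zero_p), " p-value(s) of exactly 0 clamped to ",
            format(.Machine$double.xmin), call. = FALSE)
    rec$pval[zero_p] <- .Machine$double.xmin
  }

  reason <- rep(NA_character_, nrow(rec))
  flag <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    reason[is.na(reason) & cond] <<- why
  }
  flag(!rec$ea %in% c("A", "C", "G", "T") |
       !rec$oa %in% c("A", "C", "G", "T"),
       "non_snp_allele")
  flag(rec$ea == rec$oa, "identical_alleles")
  flag(is.na(rec$beta), "missing_beta")
  flag(is.na(rec$se) | rec$se <= 0, "invalid_se")
  flag(is.na(rec$pval) | rec$pval <= 0 | rec$pval > 1, "invalid_pvalue")
  flag(!is.na(rec$eaf) & (rec$eaf <= 0 | rec$eaf >= 1), "invalid_eaf")
  flag(is.na(rec$pos) | rec$pos < 1, "invalid_position")
  flag(is.na(rec$n) | rec$n < 1, "invalid_n")

  bad <- !is.na(reason)
  drop_log <- data.frame(variant_id = rec$variant_id[bad],
                         reason = reason[bad],
                         stringsAsFactors = FALSE)
  if (nrow(drop_log))
    .msg("Dropped ", nrow(drop_log), " record(s): ",
         paste(sprintf("%s (%s)", drop_log$variant_id, drop_log$reason),
               collapse = ", "), verbose = verbose)
  rec <- rec[!bad, , drop = FALSE]
  rownames(rec) <- NULL
  new("SumStats", traitName = traitName, traitType = traitType,
      records = rec, dropLog = drop_log)
}

#' Read a GWAS summary-statistics table
#'
#' Reads a tab-separated summary-statistics file into a
#' [SumStats-class] object. The canonical header is `variant_id`, `chr`,
#' `pos`, `ea`, `oa`, `eaf`, `beta`, `se`, `pval`, `n`; foreign dialects
#' are adapted through `columnMap`.
#'
#' @param path file path.
#' @param columnMap named character vector mapping canonical field names
#'   to the file's header names, e.g.
#'   `c(variant_id = "rsids", beta = "Effect")`. Unmapped canonical
#'   fields are looked up under their own names.
#' @param traitName,traitType,verbose passed to [SumStats()];
#'   `traitName` defaults to the file name.
#' @return a [SumStats-class] object; invalid rows are dropped and
#'   recorded in its [dropLog()].
#' @export
readSumStats <- function(path, columnMap = NULL, traitName = NULL,
                         traitType = c("continuous", "binary"),
                         verbose = TRUE) {
  traitType <- match.arg(traitType)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  if (is.null(traitName))
    traitName <- sub("\\.(tsv|txt|sumstats)$", "", basename(path))
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  wanted <- stats::setNames(.SUMSTATS_COLS, .SUMSTATS_COLS)
  if (!is.null(columnMap)) {
    unknown <- setdiff(names(columnMap), .SUMSTATS_COLS)
    if (length(unknown))
      .stopf("columnMap names must be canonical fields; unknown: %s",
             paste(unknown, collapse = ", "))
    wanted[names(columnMap)] <- columnMap
  }
  missing_cols <- wanted[!wanted %in% names(raw)]
  if (length(missing_cols))
    .stopf("missing mandatory column(s) in %s: %s", path,
           paste(sprintf("%s (expected header '%s')",
                         names(missing_cols), missing_cols),
                 collapse = ", "))
  rec <- stats::setNames(raw[, wanted, drop = FALSE], names(wanted))
  SumStats(rec, traitName = traitName, traitType = traitType,
           verbose = verbose)
}

#' Write a SumStats object as a canonical tab-separated table
#'
#' Numeric fields are written with 17 significant digits so a
#' write/read round trip preserves values exactly (including p-values
#' near the smallest representable double).
#'
#' @param stats a [SumStats-class] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSumStats <- function(stats, path) {
  stopifnot(is(stats, "SumStats"))
  rec <- records(stats)
  out <- rec
  for (cl in c("eaf", "beta", "se", "pval", "n"))
    out[[cl]] <- ifelse(is.na(rec[[cl]]), "NA",
                        sprintf("%.17g", rec[[cl]]))
  out$pos <- sprintf("%.0f", rec$pos)
  con <- tryCatch(file(path, "w"),
                  error = function(e) .stopf("cannot write '%s': %s",
                                             path, conditionMessage(e)))
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @describeIn SumStats-accessors the validated per-variant records.
#' @export
setMethod("records", "SumStats", function(x) x@records)

#' @describeIn SumStats-accessors trait label.
#' @export
setMethod("traitName", "SumStats", function(x) x@traitName)

#' @describeIn SumStats-accessors `"continuous"` or `"binary"`.
#' @export
setMethod("traitType", "SumStats", function(x) x@traitType)

#' @describeIn SumStats-accessors number of retained records.
#' @export
setMethod("nVariants", "SumStats", function(x) nrow(x@records))

#' @describeIn SumStats-accessors records dropped on construction, with
#'   reasons.
#' @export
setMethod("dropLog", "SumStats", function(x) x@dropLog)

#' Accessors for SumStats objects
#' @param x a [SumStats-class] object.
#' @name SumStats-accessors
NULL

setMethod("show", "SumStats", function(object) {
  cat("SumStats object\n",
      "  trait:    ", object@traitName, " (", object@traitType, ")\n",
      "  variants: ", nrow(object@records), "\n",
      "  dropped:  ", nrow(object@dropLog), " on read\n", sep = "")
})

# replace the record table, revalidating (internal)
.replaceRecords <- function(stats, rec) {
  rownames(rec) <- NULL
  initialize(stats, records = rec)
}
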
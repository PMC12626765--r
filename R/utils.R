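# 95% normal quantile used for every interval in the package
.Z95 <- 1.959964

.complementAllele <- function(x) {
  unname(c(A = "T", T = "A", C = "G", G = "C")[x])
}

.isPalindromic <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
  (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

# Evaluate `expr` under a fixed RNG state, restoring the caller's state.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(),
                       inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic substream seeds derived from a master seed; kept inside
# 32-bit integer range.
.subSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647)
}

.msg <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(...)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# two-sided normal p-value for estimate/se
.normP <- function(beta, se) 2 * stats::pnorm(-abs(beta / se))
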
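# Small fixture builders used across the suite. Everything is
# generated in code; no stored data files.

# one-call SumStats builder with sensible filler columns
makeSumStats <- function(n = 5, variant_id = paste0("rs", seq_len(n)),
                         chr = "1", pos = seq_len(n) * 1e6,
                         ea = "A", oa = "G", eaf = 0.3,
                         beta = 0.1, se = 0.01, pval = 1e-8,
                         nSample = 1e4, traitName = "trait",
                         traitType = "continuous") {
  SumStats(data.frame(variant_id = variant_id, chr = chr, pos = pos,
                      ea = ea, oa = oa, eaf = eaf, beta = beta,
                      se = se, pval = pval, n = nSample,
                      stringsAsFactors = FALSE),
           traitName = traitName, traitType = traitType,
           verbose = FALSE)
}

# harmonized-style instrument table drawn directly (no GWAS layer):
# bx centred away from zero so Wald ratios are well behaved
makeInstruments <- function(J, seed, trueBeta = 0.5, sx = 0.005,
                            sy = 0.05, bxRange = c(0.05, 0.15),
                            interceptA = 0) {
  set.seed(seed)
  bxTrue <- sample(c(-1, 1), J, TRUE) * runif(J, bxRange[1], bxRange[2])
  bx <- bxTrue + rnorm(J, 0, sx)
  by <- interceptA * sign(bxTrue) + trueBeta * bxTrue + rnorm(J, 0, sy)
  data.frame(variant_id = paste0("iv", seq_len(J)), bx = bx,
             sx = sx, by = by, sy = sy)
}

emptyLD <- function(ids) ldSource(domain = ids)
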
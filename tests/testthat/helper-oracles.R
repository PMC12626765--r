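# Independent oracles: brute-force / generic-tool re-implementations
# kept deliberately separate from the package's computation paths.

# weighted least squares through the origin via lm()
oracle_ivw <- function(bx, by, sy) {
  fit <- lm(by ~ 0 + bx, weights = 1 / sy^2)
  s <- summary(fit)
  seScaled <- s$coefficients[1, 2]          # includes sigma
  seFixed <- seScaled / s$sigma             # unit-variance weights
  list(beta = unname(coef(fit)[1]), seFixed = seFixed,
       seRandom = seFixed * max(1, s$sigma))
}

# weighted regression with intercept via lm(); caller re-orients first
oracle_egger <- function(bx, by, sy) {
  fit <- lm(by ~ bx, weights = 1 / sy^2)
  s <- summary(fit)
  sigma <- s$sigma
  scale <- max(1, sigma)
  list(intercept = unname(coef(fit)[1]), beta = unname(coef(fit)[2]),
       interceptSe = s$coefficients[1, 2] / sigma * scale,
       se = s$coefficients[2, 2] / sigma * scale)
}

# weighted median by explicit loop over the cumulative weights
oracle_weighted_median <- function(theta, w) {
  o <- order(theta)
  theta <- theta[o]
  w <- w[o] / sum(w)
  cum <- 0
  p <- numeric(length(w))
  for (j in seq_along(w)) {
    p[j] <- cum + w[j] / 2
    cum <- cum + w[j]
  }
  below <- max(which(p < 0.5), 1)
  if (p[below] >= 0.5) return(theta[1])
  if (below == length(p)) return(theta[length(p)])
  above <- below + 1
  theta[below] + (theta[above] - theta[below]) *
    (0.5 - p[below]) / (p[above] - p[below])
}

# dense-grid kernel density maximization (100001 points)
oracle_mode <- function(theta, w, phi = 1) {
  w <- w / sum(w)
  h <- phi * 0.9 * min(sd(theta), mad(theta)) * length(theta)^(-1 / 5)
  if (!is.finite(h) || h <= 0) return(theta[1])
  grid <- seq(min(theta) - 3 * h, max(theta) + 3 * h,
              length.out = 100001L)
  dens <- vapply(grid, function(x) sum(w * dnorm(x, theta, h)),
                 numeric(1))
  grid[which.max(dens)]
}

# exhaustive greedy clumping on an explicit r2 matrix
oracle_clump <- function(df, r2mat, r2Max, windowBp) {
  kept <- character()
  pool <- df[order(df$pval, df$chr, df$pos, df$variant_id), ]
  while (nrow(pool) > 0) {
    top <- pool[1, ]
    kept <- c(kept, top$variant_id)
    drop <- pool$chr == top$chr &
      abs(pool$pos - top$pos) <= windowBp &
      r2mat[top$variant_id, pool$variant_id] >= r2Max
    drop[1] <- TRUE
    pool <- pool[!drop, , drop = FALSE]
  }
  kept
}

# rule-table enumeration of the harmonization action for one pair.
# Exposure alleles (eaX/oaX), outcome representation (eaY/oaY), plus
# frequencies; returns list(action, flip).
oracle_harmonize_pair <- function(eaX, oaX, eaY, oaY, eafX, eafY,
                                  policy = "resolve_by_eaf",
                                  band = 0.08, allowStrand = TRUE) {
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  palindrome <- paste0(eaX, oaX) %in% c("AT", "TA", "CG", "GC")
  if (palindrome) {
    if (!setequal(c(eaY, oaY), c(eaX, oaX)))
      return(list(action = "dropped_mismatch", flip = FALSE))
    if (policy == "drop_all" || is.na(eafX) || is.na(eafY) ||
        abs(eafX - 0.5) <= band || abs(eafY - 0.5) <= band)
      return(list(action = "dropped_palindromic", flip = FALSE))
    # orient by minor-allele side: the exposure effect allele is the
    # outcome effect allele iff both frequencies sit on the same side
    # of 0.5 after nominal label alignment
    nominalFlip <- eaY != eaX
    f <- if (nominalFlip) 1 - eafY else eafY
    flip <- if ((eafX < 0.5) == (f < 0.5)) nominalFlip else !nominalFlip
    return(list(action = if (flip) "kept_flipped" else "kept_same",
                flip = flip))
  }
  if (eaY == eaX && oaY == oaX)
    return(list(action = "kept_same", flip = FALSE))
  if (eaY == oaX && oaY == eaX)
    return(list(action = "kept_flipped", flip = TRUE))
  if (allowStrand && comp[eaY] == eaX && comp[oaY] == oaX)
    return(list(action = "kept_strand_flipped", flip = FALSE))
  if (allowStrand && comp[eaY] == oaX && comp[oaY] == eaX)
    return(list(action = "kept_strand_flipped", flip = TRUE))
  list(action = "dropped_mismatch", flip = FALSE)
}
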
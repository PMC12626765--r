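# ---- internal cores -------------------------------------------------
# The cores operate on bare numeric vectors; the exported functions
# wrap them with input handling and MREstimate construction.

.ivwCore <- function(bx, by, sy) {
  w <- 1 / sy^2
  beta <- sum(w * bx * by) / sum(w * bx^2)
  seFixed <- sqrt(1 / sum(w * bx^2))
  J <- length(bx)
  qResid <- sum(w * (by - beta * bx)^2)
  scale <- if (J > 1L) max(1, sqrt(qResid / (J - 1L))) else 1
  list(beta = beta, seFixed = seFixed, seRandom = seFixed * scale,
       scale = scale, qResid = qResid, J = J)
}

.eggerCore <- function(bx, by, sy, reorient = TRUE) {
  if (reorient) {
    s <- ifelse(bx < 0, -1, 1)
    bx <- bx * s
    by <- by * s
  }
  J <- length(bx)
  w <- 1 / sy^2
  sw <- sum(w); swx <- sum(w * bx); swx2 <- sum(w * bx^2)
  swy <- sum(w * by); swxy <- sum(w * bx * by)
  det <- sw * swx2 - swx^2
  alpha <- (swx2 * swy - swx * swxy) / det
  beta  <- (sw * swxy - swx * swy) / det
  rss <- sum(w * (by - alpha - beta * bx)^2)
  scale <- if (J > 2L) max(1, sqrt(rss / (J - 2L))) else 1
  seBeta  <- sqrt(sw / det) * scale
  seAlpha <- sqrt(swx2 / det) * scale
  list(beta = beta, se = seBeta, intercept = alpha, interceptSe = seAlpha,
       df = J - 2L, scale = scale)
}

# weighted median by linear interpolation of the cumulative-midpoint
# weights; `w` need not be normalized
.weightedMedianCore <- function(theta, w) {
  ord <- order(theta)
  theta <- theta[ord]
  w <- w[ord] / sum(w)
  p <- cumsum(w) - w / 2
  stats::approx(p, theta, xout = 0.5, rule = 2, ties = "ordered")$y
}

# kernel-density mode over a 512-point grid spanning range(theta) +- 3h
.modeCore <- function(theta, w, phi = 1) {
  w <- w / sum(w)
  s <- stats::sd(theta)
  m <- stats::mad(theta)  # default constant 1.4826 = 1/0.6745
  h <- phi * 0.9 * min(s, m) * length(theta)^(-1 / 5)
  if (!is.finite(h) || h <= 0) return(theta[1])
  grid <- seq(min(theta) - 3 * h, max(theta) + 3 * h, length.out = 512L)
  dens <- colSums(w * outer(theta, grid, function(t, x)
    stats::dnorm(x, mean = t, sd = h)))
  grid[which.max(dens)]
}

.asInstrumentTable <- function(x) {
  d <- if (is(x, "HarmonizedSet")) keptInstruments(x) else as.data.frame(x)
  need <- c("bx", "sx", "by", "sy")
  missing <- setdiff(need, names(d))
  if (length(missing))
    .stopf("instrument table lacks columns: %s",
           paste(missing, collapse = ", "))
  d
}

.outcomeType <- function(x, default = "continuous") {
  if (is(x, "HarmonizedSet")) x@outcomeType else default
}

.mrEstimate <- function(method, beta, se, pvalue, nSNPs, binary,
                        ciQuantile = .Z95) {
  ciLow <- beta - ciQuantile * se
  ciHigh <- beta + ciQuantile * se
  new("MREstimate", method = method, beta = beta, se = se,
      pvalue = pvalue, ciLow = ciLow, ciHigh = ciHigh,
      nSNPs = as.integer(nSNPs),
      oddsRatio = if (binary) exp(beta) else NA_real_,
      orCiLow = if (binary) exp(ciLow) else NA_real_,
      orCiHigh = if (binary) exp(ciHigh) else NA_real_)
}

# parametric bootstrap of a ratio-based estimator: resample each Wald
# ratio from Normal(theta_j, se_j) and recompute the point estimate
.bootstrapSe <- function(theta, thetaSe, pointFun, nBoot, seed) {
  if (nBoot <= 0L) return(NA_real_)
  .withSeed(seed, {
    est <- vapply(seq_len(nBoot), function(i) {
      pointFun(stats::rnorm(length(theta), theta, thetaSe))
    }, numeric(1))
    stats::sd(est)
  })
}

# ---- exported estimators --------------------------------------------

#' Wald ratio for a single instrument
#'
#' beta = by / bx with first-order standard error sy / |bx|.
#'
#' @param inst a one-row instrument table (or [HarmonizedSet-class]
#'   with one kept instrument) with columns `bx`, `sx`, `by`, `sy`.
#' @param binary whether the outcome is binary (populates odds-ratio
#'   fields).
#' @return an [MREstimate-class] object.
#' @export
mrWaldRatio <- function(inst, binary = FALSE) {
  d <- .asInstrumentTable(inst)
  binary <- binary || .outcomeType(inst) == "binary"
  if (nrow(d) != 1L) .stopf("wald ratio requires exactly 1 instrument")
  if (d$bx == 0) .stopf("degenerate instrument: bx = 0")
  beta <- d$by / d$bx
  se <- d$sy / abs(d$bx)
  .mrEstimate("wald_ratio", beta, se, .normP(beta, se), 1L, binary)
}

#' Inverse-variance weighted estimator
#'
#' Weighted regression of outcome on exposure effects through the
#' origin with weights 1/sy^2: beta = sum(w bx by) / sum(w bx^2).
#' The fixed-effects SE is (sum(w bx^2))^(-1/2); the multiplicative
#' random-effects SE (the default, matching common two-sample MR
#' practice for heterogeneous instruments) inflates it by
#' max(1, sqrt(Q_resid / (J - 1))), so it never falls below the fixed
#' SE. With a single instrument the estimate falls back to the Wald
#' ratio, with a message.
#'
#' @param instruments a [HarmonizedSet-class] or data.frame with
#'   columns `bx`, `sx`, `by`, `sy`.
#' @param model `"multiplicative_random"` (default) or `"fixed"`.
#' @param binary whether the outcome is binary.
#' @return an [MREstimate-class] object.
#' @export
mrIVW <- function(instruments, model = c("multiplicative_random", "fixed"),
                  binary = FALSE) {
  model <- match.arg(model)
  d <- .asInstrumentTable(instruments)
  binary <- binary || .outcomeType(instruments) == "binary"
  if (nrow(d) == 0L) .stopf("IVW requires at least 1 instrument")
  if (nrow(d) == 1L) {
    message("single instrument: falling back to Wald ratio")
    return(mrWaldRatio(d, binary = binary))
  }
  core <- .ivwCore(d$bx, d$by, d$sy)
  se <- if (model == "fixed") core$seFixed else core$seRandom
  .mrEstimate("ivw", core$beta, se, .normP(core$beta, se), nrow(d), binary)
}

#' MR-Egger regression
#'
#' Weighted linear regression by = alpha + beta * bx with weights
#' 1/sy^2, after re-orienting instruments so all bx >= 0 (negating both
#' members of a pair), since the intercept is orientation-dependent.
#' The intercept alpha estimates average directional pleiotropy.
#' Standard errors are inflated by max(1, residual scale) with J - 2
#' degrees of freedom; inference (p-values and CIs) uses t quantiles
#' with J - 2 df, which protects the small-J intercept test.
#'
#' @inheritParams mrIVW
#' @return list with elements `slope` (an [MREstimate-class]),
#'   `intercept`, `interceptSe`, `interceptPvalue`.
#' @export
mrEgger <- function(instruments, binary = FALSE) {
  d <- .asInstrumentTable(instruments)
  binary <- binary || .outcomeType(instruments) == "binary"
  if (nrow(d) < 3L)
    .stopf("MR-Egger requires >= 3 instruments (got %d)", nrow(d))
  core <- .eggerCore(d$bx, d$by, d$sy, reorient = TRUE)
  tq <- stats::qt(0.975, df = core$df)
  slopeP <- 2 * stats::pt(-abs(core$beta / core$se), df = core$df)
  interceptP <- 2 * stats::pt(-abs(core$intercept / core$interceptSe),
                              df = core$df)
  slope <- .mrEstimate("egger", core$beta, core$se, slopeP, nrow(d),
                       binary, ciQuantile = tq)
  list(slope = slope, intercept = core$intercept,
       interceptSe = core$interceptSe, interceptPvalue = interceptP)
}

#' Weighted median estimator
#'
#' Per-instrument Wald ratios theta_j are weighted by bx_j^2 / sy_j^2
#' (normalized); the estimate is the linear interpolation of the sorted
#' ratios at cumulative-midpoint weight 0.5. Consistent when at least
#' half the total weight comes from valid instruments. The SE comes
#' from a seeded parametric bootstrap: each ratio is resampled from
#' Normal(theta_j, se_j) with first-order se_j = sy_j / |bx_j| and the
#' median recomputed.
#'
#' @inheritParams mrIVW
#' @param nBoot bootstrap replicates (default 1000; 0 skips the SE, in
#'   which case se/p-value/CI are `NA`).
#' @param seed bootstrap seed.
#' @return an [MREstimate-class] object.
#' @export
mrWeightedMedian <- function(instruments, nBoot = 1000L, seed = 1L,
                             binary = FALSE) {
  d <- .asInstrumentTable(instruments)
  binary <- binary || .outcomeType(instruments) == "binary"
  if (nrow(d) < 3L)
    .stopf("weighted median requires >= 3 instruments (got %d)", nrow(d))
  theta <- d$by / d$bx
  w <- d$bx^2 / d$sy^2
  beta <- .weightedMedianCore(theta, w)
  se <- .bootstrapSe(theta, d$sy / abs(d$bx),
                     function(th) .weightedMedianCore(th, w), nBoot, seed)
  .mrEstimate("weighted_median", beta, se,
              if (is.na(se)) NA_real_ else .normP(beta, se), nrow(d),
              binary)
}

#' Mode-based estimators (simple and weighted)
#'
#' The estimate is the argmax of a normal-kernel density of the
#' per-instrument Wald ratios, evaluated on a 512-point grid spanning
#' range(theta) +- 3h, with bandwidth
#' h = phi * 0.9 * min(sd(theta), mad(theta) / 0.6745) * J^(-1/5).
#' The weighted variant uses kernel weights bx_j^2 / sy_j^2
#' (normalized); the simple variant weighs instruments equally. If all
#' ratios coincide the bandwidth degenerates and the common ratio is
#' returned. SE by seeded parametric bootstrap as in
#' [mrWeightedMedian()].
#'
#' @inheritParams mrWeightedMedian
#' @param weighted logical; weighted or simple mode.
#' @param phi bandwidth multiplier (default 1).
#' @return an [MREstimate-class] object.
#' @export
mrMode <- function(instruments, weighted = FALSE, phi = 1,
                   nBoot = 1000L, seed = 1L, binary = FALSE) {
  d <- .asInstrumentTable(instruments)
  binary <- binary || .outcomeType(instruments) == "binary"
  if (nrow(d) < 3L)
    .stopf("mode estimator requires >= 3 instruments (got %d)", nrow(d))
  stopifnot(phi > 0)
  theta <- d$by / d$bx
  w <- if (weighted) d$bx^2 / d$sy^2 else rep(1, nrow(d))
  beta <- .modeCore(theta, w, phi = phi)
  se <- .bootstrapSe(theta, d$sy / abs(d$bx),
                     function(th) .modeCore(th, w, phi = phi), nBoot, seed)
  .mrEstimate(if (weighted) "weighted_mode" else "simple_mode",
              beta, se,
              if (is.na(se)) NA_real_ else .normP(beta, se), nrow(d),
              binary)
}

#' Cochran's Q heterogeneity test on Wald ratios
#'
#' With theta_j = by_j / bx_j and first-order variances
#' v_j = (sy_j / bx_j)^2, Q = sum((theta_j - theta_ivw)^2 / v_j) where
#' theta_ivw is the inverse-variance weighted mean of the ratios; the
#' p-value is from a chi-square with J - 1 degrees of freedom.
#'
#' @inheritParams mrIVW
#' @return list with `qStat`, `qDf`, `qPvalue`.
#' @export
cochranQ <- function(instruments) {
  d <- .asInstrumentTable(instruments)
  if (nrow(d) < 2L)
    .stopf("Cochran's Q requires >= 2 instruments (got %d)", nrow(d))
  theta <- d$by / d$bx
  v <- (d$sy / d$bx)^2
  thetaIvw <- sum(theta / v) / sum(1 / v)
  q <- sum((theta - thetaIvw)^2 / v)
  df <- nrow(d) - 1L
  list(qStat = q, qDf = df,
       qPvalue = stats::pchisq(q, df = df, lower.tail = FALSE))
}

#' Cross-method direction consistency
#'
#' TRUE iff all supplied causal estimates are strictly positive or all
#' strictly negative; an exact zero counts as inconsistent.
#'
#' @param betas numeric vector of the five methods' point estimates
#'   (or a list of [MREstimate-class] objects).
#' @return logical(1).
#' @export
directionConsistent <- function(betas) {
  if (is.list(betas))
    betas <- vapply(betas, function(e) e@beta, numeric(1))
  if (anyNA(betas)) .stopf("missing method estimate")
  all(betas > 0) || all(betas < 0)
}

setMethod("show", "MREstimate", function(object) {
  cat(sprintf("MREstimate [%s]  beta = %.4g (se %.4g), p = %.3g, J = %d\n",
              object@method, object@beta, object@se, object@pvalue,
              object@nSNPs))
  if (!is.na(object@oddsRatio))
    cat(sprintf("  OR = %.4g (95%% CI %.4g - %.4g)\n", object@oddsRatio,
                object@orCiLow, object@orCiHigh))
})
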
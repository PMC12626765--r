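---
title: "Two-step MR screening and mediation: models, choices, limits"
author: "mrcascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step MR screening and mediation: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrcascade)
```

## The problem this package addresses

Metabolome-wide Mendelian randomization (MR) asks whether circulating
metabolites causally transmit part of an exposure's effect on a
disease. The canonical design is two-step: first screen many
metabolites for a causal effect on the outcome (metabolite →
disease), then test whether the exposure shifts the surviving
metabolites (exposure → metabolite), and finally quantify, for a
metabolite that passes both arms, what share of the exposure's total
effect flows through it. `mrcascade` implements that entire pipeline
for GWAS summary statistics — instrument selection, allele
harmonization, five causal estimators with a sensitivity battery, the
multi-stage filter cascade, and product-of-coefficients mediation —
plus a synthetic GWAS generator with a known causal triad so every
stage can be validated without external data.

## Models and estimators

### Instruments

For each exposure we keep variants that pass a p-value threshold
(1e-5 is the working default for modestly powered metabolite GWAS;
5e-8 for large-biobank anthropometric traits), prune them to
approximate independence by greedy LD clumping (pairwise r² < 0.001
within a 10 Mb window, lowest p kept first, ties broken by genomic
position so the result is independent of row order), and discard weak
instruments. Strength is measured through the variance explained

R² = 2β²f(1−f) / (2β²f(1−f) + 2·SE²·N·f(1−f)),

which simplifies algebraically to β²/(β² + SE²·N) — the
allele-frequency factor cancels; the package computes the short form
and the test suite asserts equality of both to 1e-12 — and the
F-statistic F = R²(N−2)/(1−R²), with the conventional F > 10 cutoff
(strictly greater). Boundary behaviour everywhere is: selection p
strictly below threshold, clump discard at r² at-or-above threshold,
F strictly above the cutoff.

### Harmonization

Exposure and outcome effects must refer to the same allele.
Non-palindromic variants match directly, by allele swap (outcome
effect negated, frequency complemented), or — when
`allowStrandFlip = TRUE`, the default, appropriate for source GWAS
genotyped on multiple platforms — by strand complement. Palindromic
(A/T, C/G) variants carry no strand information in their alleles; the
default policy infers orientation from allele frequency and drops the
variant when either trait's frequency lies within 0.08 of 0.5 (or is
missing). A frequency of exactly 0.5 on either side is uninformative
no matter what the other side shows, which is why the band applies to
either frequency rather than requiring both to be ambiguous. Every
input instrument is accounted for in the output: kept actions record
how the alignment was achieved, dropped actions record why.

### The five estimators

All estimators consume harmonized pairs (bx, sx, by, sy).

* **IVW** (primary): weighted regression of by on bx through the
  origin with weights 1/sy², equivalent to the inverse-variance
  weighted mean of per-variant Wald ratios. The default
  random-effects flavour is multiplicative: the fixed-effects
  standard error is inflated by max(1, √(Q_resid/(J−1))). The floor
  at 1 means the SE is never deflated below fixed-effects; the price
  is mild conservativeness under perfect homogeneity (the measured
  null rejection rate in our validation runs is ≈3.5–4% at nominal
  5%, because the inflation factor exceeds 1 half the time by
  chance).
* **MR-Egger**: the same regression with a free intercept, which
  absorbs directional pleiotropy. Because the intercept depends on
  instrument orientation, instruments are re-oriented so all bx ≥ 0
  before fitting; this is applied inside the estimator so all other
  methods see the harmonized pairs untouched. Inference uses t
  quantiles with J−2 degrees of freedom — normal quantiles are
  anti-conservative for the small instrument counts typical of
  metabolite GWAS.
* **Weighted median**: per-variant ratios weighted by bx²/sy²,
  linearly interpolated at cumulative-midpoint weight 0.5; consistent
  when valid instruments carry at least half the weight.
* **Simple and weighted mode**: the argmax of a normal-kernel density
  of the ratios over a 512-point grid spanning the ratio range ± 3
  bandwidths, with bandwidth h = φ·0.9·min(sd, mad/0.6745)·J^(−1/5)
  and φ = 1 by default. If all ratios coincide the bandwidth
  degenerates and the common ratio is returned.

Median and mode standard errors come from a seeded parametric
bootstrap (each ratio resampled from its first-order normal, 1000
draws by default); point estimates never depend on the bootstrap, so
screening runs may set `nBoot = 0` and skip it.

### Sensitivity battery

Cochran's Q on the Wald ratios with first-order variances
(chi-square, J−1 df) tests heterogeneity; the regression-residual
dispersion differs from it only at second order and is used solely
inside the IVW scale factor. The Egger intercept t-test flags
directional pleiotropy. Direction consistency demands a strict shared
sign across all five point estimates (an exact zero is inconsistent).
A reverse-MR arm swaps the roles and records the IVW p-value; its
instrument threshold defaults to 1e-5 rather than 5e-8 because
disease outcomes such as a rare cancer rarely have genome-wide hits
at the stricter level — this choice is logged in every battery
configuration. All sensitivity verdicts use two-sided α = 0.05 by
default, configurable.

### The filter cascade

`step1Screen()` (metabolites → outcome) and `step2Screen()`
(exposure → metabolites) apply the same ordered filters: IVW
significance, direction consistency, pleiotropy exclusion,
heterogeneity exclusion, reverse-MR exclusion. The order is fixed
because the audit counts are part of the result; a `CascadeAudit`
records entering/passing counts and per-trait drop reasons at every
stage, with conservation (entering = passing + dropped) enforced by
the class validity. Estimator failures (for example, fewer than three
usable instruments) are recorded as drops at an initial estimation
stage and never abort a batch. Following the source protocol the
cascade applies **no multiple-testing correction** — raw p < 0.05 at
the IVW stage; a Benjamini–Hochberg variant is available
(`padjust = "BH"`) but off by default. The consequence is worth
stating plainly: screening k null traits passes roughly 3.5–5% of
them through the IVW stage, and the downstream filters remove only
part of those, so occasional false survivors are expected behaviour
of the protocol, not a defect of the implementation.

### Mediation

With β_EM (exposure→mediator), β_MO (mediator→outcome) and β_EO
(total exposure→outcome) estimated by IVW on non-overlapping GWAS,
the indirect effect is β_EM·β_MO with first-order delta SE
√(β_MO²·se_EM² + β_EM²·se_MO²), and the mediation proportion is
β_EM·β_MO/β_EO. For the proportion interval the default
(`fixed_total`) treats β_EO as fixed and divides the indirect
effect's normal 95% bounds by it. The total effect is typically
estimated far more precisely than the indirect effect, and this
choice reproduces published proportion intervals computed from
printed coefficients; a `full_delta` variant that also propagates
se_EO through the ratio is provided and is wider. Printed confidence
intervals can be converted back to standard errors with
`reconstructSeFromCi()` (interval width divided by 2 × 1.959964), so
published worked examples are reproducible without any GWAS input
(`runMediation()` mode `from_coefficients`). Reported tables round
effects to 3 decimals and proportions to 3 significant figures of the
rounded-indirect-to-total ratio, matching the field's display
convention; objects keep full precision.

## The synthetic generator

`triadModel()`/`simulateTriad()` encode an exposure → mediator →
outcome chain: per-instrument true effects are drawn with random
signs inside configurable magnitude ranges, propagated along the
chain (mediator effect a·α, outcome effect (c′ + a·b)·α for exposure
instruments; b·γ for mediator instruments), and observed with
sampling noise se = 1/√(2·N_eff·f(1−f)). The defaults are the study
conditions the validation suite runs under: a UK-Biobank-scale
continuous exposure (N = 330,762, effects 0.02–0.06 SD), a
CLSA-scale metabolite GWAS (N = 8,299, effects 0.08–0.20 SD), and a
FinnGen-scale binary outcome with extreme case-control imbalance
(855 cases of 345,973; N_eff = 4v(1−v)N ≈ 3,413; instrument effects
0.20–0.45 log-odds), with a = 0.2, b = 0.3, c′ = 0.3, so the true
total effect is 0.36 and the true mediated proportion 16.7%. That
outcome imbalance is deliberately punishing — it is what makes
rare-cancer MR confidence intervals wide — and it dominates the
variance of every outcome-side estimate in the simulations.

Three contamination channels exercise the sensitivity battery:
directional pleiotropy (a fraction of exposure instruments receive a
direct outcome effect aligned with the exposure-increasing allele, so
it survives Egger's bx ≥ 0 re-orientation — sign-balanced pleiotropy
would cancel out of the intercept by construction), multiplicative
heterogeneity inflation of the observed outcome effects with nominal
reported SEs, and reverse-causal instruments (outcome variants whose
mediator association is downstream). Variants sit on one synthetic
chromosome at uniform 100 kb spacing; the emitted LD table declares
all variants independent unless LD blocks are requested
(`ldBlockSize`, `ldBlockR2`), which exist to exercise clumping.
Mediator and outcome records are randomly re-expressed (allele
swaps, strand complements) so harmonization is always on the live
path. All randomness flows from one seed through fixed substreams;
identical models give bit-identical output.

What the generator does **not** emulate: real LD structure from a
reference panel, allele-frequency spectra with rare variants,
population stratification, sample overlap between GWAS, winner's
curse beyond the explicit selection thresholds, and non-normal effect
distributions. Passing tests therefore demonstrate the statistical
machinery under the stated sampling model, not robustness to every
pathology of real consortium data.

## Validation experiments and their problem sizes

The acceptance suite (and `scripts/acceptance.R`) recomputes, at
sizes chosen to finish in minutes on one core: estimator agreement
with independent brute-force oracles on 50-instrument sets (normal
equations, direct interpolation, independently coded grid
maximization; 1e-8 relative); the IVW null rejection rate over 1000
global-null replicates; IVW interval coverage of the true effect over
2000 homogeneous replicates; the median recovered mediation
proportion over 500 triads against the 16.7% truth; and the step-1
cascade's operating characteristics over 100 screens of 20
metabolites (3 causal, instrument effects raised to 0.3–0.5 SD so
the causal arm is well powered).

Two honest observations from those runs. First, the floored
random-effects IVW is slightly conservative under the null (≈3.5%
rejection at nominal 5%), as discussed above. Second, the cascade
cannot jointly deliver "all causal traits recovered and zero false
survivors" at high frequency: raw-α screening passes a few percent of
nulls, and the reverse-MR stage — lacking any instrument-overlap
guard — wrongly flags a truly causal metabolite in roughly a fifth of
screens at high instrument strength, because the metabolite's own
instruments acquire outcome associations b·γ strong enough to enter
the reverse arm, where they mimic reverse causation with apparent
effect 1/b. Steiger filtering would mitigate this, but it is outside
the protocol implemented here; the behaviour is reported as measured.

## Known limitations

* No MR-PRESSO outlier removal, Steiger directionality filtering,
  multivariable MR, or mediator-adjusted two-step MR; single mediator
  per mediation call.
* LD handling requires a precomputed pairwise r² table; variants
  outside its declared domain are conservatively treated as
  independent (with a warning), and no proxy-instrument search is
  attempted.
* The mediation proportion interval treats the total effect as fixed
  by default; when β_EO is small or imprecise the `full_delta`
  variant is the safer report.
* Binary-outcome effects are assumed to be log-odds; the
  effective-sample-size SE approximation degrades for very common
  diseases or non-European-style imbalances only in the sense that
  N_eff is an approximation, not a property of the estimators.
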
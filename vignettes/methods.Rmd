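---
title: "Methods: two-sample Mendelian randomization in gwasMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomization in gwasMR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwasMR)
```

# Scope and data model

gwasMR implements the complete summary-statistics workflow for asking
whether a heritable exposure causally affects an outcome: instrument
selection, allele harmonization, five causal estimators, a sensitivity
suite, multivariable MR, LD score regression (LDSC), and power. The
central objects are S4 classes: `SummaryStats` (one trait's per-variant
association table plus trait metadata), `LDReference` (variant index,
sparse pairwise r², per-variant LD scores), `HarmonizedSet` (the
allele-aligned estimator input), `MREstimate`, `PressoReport` and
`LDSCResult`. Effects for binary traits are log-odds throughout; odds
ratios are computed only at serialization, which avoids
double-exponentiation mistakes.

Variants are matched across datasets by rsID, never by position, so the
genome build is opaque metadata and no liftover is needed. Alleles are
uppercased on read; p-values of exactly zero are clamped to the
smallest positive double so downstream log/quantile operations stay
finite; rows whose mandatory numerics fail to parse are dropped and
counted in an audit log. Each filtering stage reports removal counts,
and the chain is conservative: input count = output count + removals,
at every stage.

# Instrument selection

Selection composes four filters with the conventional thresholds:

* genome-wide significance, strict inequality `P < 5e-8`;
* greedy LD clumping: take the smallest-p remaining candidate as index,
  remove candidates on the same chromosome within ±10,000 kb whose
  r² ≥ 0.001 against it, repeat. Ties on p keep the smaller
  coordinate, then the lexicographically smaller rsID, so results are
  deterministic. Distant same-chromosome variants are never removed
  regardless of r² — the window is part of the rule. Candidates absent
  from the LD reference are treated as independent and logged.
* weak-instrument filter `F = beta^2/se^2 > 10` (strict);
* the Steiger filter, which needs outcome data and therefore runs after
  harmonization (below).

Proxy lookup (`r² > 0.8`, argmax with nearest-position then rsID
tie-breaks) is implemented but disabled by default: the primary
analysis this package models uses no proxies, and enabling them is a
single config flag. Per-variant metrics report both individual F
statistics and the mean across instruments, plus
`R² = 2·MAF·(1−MAF)·beta²` with total instrument R² as the sum —
`beta` is assumed to be on a standardized-trait scale, which is the
caller's responsibility and matters for the absolute (not relative)
value of R².

# Harmonization

Outcome effects are aligned to the exposure's effect allele: identical
pairs are kept, swapped pairs negate the outcome beta and reflect its
eaf, pairs matching after strand complement are complemented first.
Palindromic variants (A/T, C/G) cannot be resolved from alleles; under
the default policy `"infer"` they are kept when both effect-allele
frequencies are on the same side of 0.5 **and** both lie outside the
ambiguity zone [0.42, 0.58] — a widely used convention; the zone width
is exposed in config because no principled universal value exists.
Policy `"drop"` removes all palindromes; missing frequencies also drop
them. Multi-allelic/indel rows are dropped with reason. Two properties
pin the implementation: harmonizing a dataset against itself is the
identity, and flipping the reported effect allele of every outcome
record (allele swap, beta sign, eaf reflection) leaves the result
unchanged.

# Estimators

With k instruments, per-variant Wald ratios `r_j = by_j/bx_j` carry
first-order variances `v_j = sey_j^2/bx_j^2` (the second-order term
`by^2 sex^2 / bx^4` is available behind a flag; first-order is the
common default). IVW is the 1/v-weighted mean, identical by algebra to
weighted regression through the origin — both routes are computed in
the tests and must agree to 1e-10. The multiplicative random-effects
standard error multiplies the fixed-effect one by `sqrt(max(1,
Q/(k-1)))`; the floor at 1 (no under-dispersion credit) is deliberate
and affects borderline intervals. The primary IVW is labelled
fixed-effects when I² < 50% and random-effects otherwise; both are
always reported rather than silently chosen, because the two can lead
to different conclusions.

MR-Egger regresses by on bx with a free intercept and weights
1/sey², after orienting rows so bx ≥ 0 (the slope is invariant to this
orientation only with the intercept present, hence the explicit flip).
Slope = causal estimate under InSIDE, intercept = average directional
pleiotropy; standard errors carry `sqrt(max(1, sigma2_resid))` and
p-values use t with k−2 df.

The weighted median orders ratios and interpolates the standardized
cumulative weights `s_j = (cumsum(w) − w/2)/sum(w)` at 0.5; its
standard error comes from a parametric bootstrap (per-variant betas
resampled from their sampling normals, default 1,000 draws, seed
recorded). The mode estimators maximise a normal-kernel density of the
ratios with bandwidth `phi × 0.9 × min(sd, mad) × k^(−1/5)` — a
MAD-based rule of thumb, pinned here because the bandwidth is part of
the estimator's definition; `phi` defaults to 1, and the weighted
variant weights the kernel by 1/v. P-values are normal-theory for
ratio/IVW/median/mode and t-based for Egger.

# Sensitivity suite

Cochran's Q with `I² = max(0, (Q−df)/Q)·100`; the Egger intercept
test; leave-one-out IVW (k rows plus an all-SNP reference row); a
funnel table (ratio vs 1/se of the ratio, no statistic — asymmetry is a
visual pleiotropy diagnostic); and MR-PRESSO.

MR-PRESSO simulates the no-pleiotropy model: observed weighted squared
residuals from leave-one-out IVW predictions are compared against
`nSim` parametric draws (`bx* ~ N(bx, sex)`, `by* ~ N(b_loo·bx, sey)`).
The global p-value is the RSS exceedance fraction; per-variant outlier
p-values compare each residual with its own simulated null,
Bonferroni-flagged at 0.05/k (the reference implementation's
convention). The distortion test compares the outlier-free estimate's
shift from the full estimate against shifts of `nSim` random subsets of
the same size — the original method's description leaves the resampling
scheme open; this choice uses one budget knob for all three tests. The
corrected estimate exists only when an outlier is flagged. Empirical
p-values use the (1+exceed)/(1+nSim) form, so `nSim` bounds their
resolution: outlier flagging at 0.05/k needs `nSim > k/0.05`, which the
default `nSim = 1000` satisfies for k ≤ 50.

The Steiger test compares per-variant variance explained:
`2·maf·(1−maf)·beta²` when frequencies are available, falling back to
`F/(F+n−2)` otherwise; binary outcomes are put on the observed
log-odds scale by the factor K(1−K), K the case fraction — scale choice
changes borderline flags, so it is stated prominently. A variant is
kept when it explains strictly more exposure variance; the overall
direction compares summed r² over kept variants, with a
two-correlation Fisher-z test for its p-value. Steiger filtering runs
after harmonization and before estimation.

# Multivariable MR

Joint instruments are the union of each exposure's significant
variants, jointly clumped by minimum p across exposures (the selection
rule is not uniquely standard; the union rule is the default and
documented). All traits are harmonized to the first exposure's
orientation. The fit is weighted multiple regression of by on the
exposure-effect matrix with no intercept and weights 1/sey²;
per-exposure standard errors carry the same multiplicative
random-effects floor with df = rows − exposures. An all-zero exposure
column is reported as a zero direct effect rather than an error; truly
collinear exposures raise an error naming the offending pair.
Per-exposure Wald chi-squares from the same fit are attached as
instrument-strength diagnostics (labelled extra — conditional-strength
reporting is good MVMR hygiene even where not requested). The pipeline
adjusts one covariate at a time, mirroring the individual-adjustment
design; a joint model sits behind `joint = TRUE`. Per-covariate
failures are isolated so one bad covariate cannot abort the rest.

# LD score regression

Univariate: regress z² on `n·l/m` with a free intercept; the slope is
h², the intercept (expected 1) absorbs confounding and overlap.
Weights combine the 1/l oversampling correction with the
heteroskedasticity weight `1/(2(1+n·h²·l/m)²)` in two passes (h² = 0,
then the first-pass slope) — the weighting must be pinned to be
reproducible. Cross-trait: regress z₁z₂ on `sqrt(n1·n2)·l/m`; the
slope is the genetic covariance and `rg = cov_g/sqrt(h²₁·h²₂)`.
Cross-regression weights are `1/l · 1/(v₁v₂)` with v built from each
trait's first-pass h²: these are proportional to the univariate
second-pass weights when the two traits coincide, which makes
`estimateRg(t, t)` return exactly 1 — a structural identity the tests
assert. Uncertainty is a delete-one block jackknife over contiguous
variant blocks (contiguity proxies genomic order), default 200 blocks,
automatically reduced for small inputs; the rg jackknife refits the
full ratio per deleted block. rg is clamped to [−1, 1] with a flag;
non-positive h² makes rg undefined (degenerate flag) rather than a
number. Constant LD scores leave slope and intercept unidentifiable
and are flagged. There is no constrained-intercept mode.

# Power

The binary-outcome power uses the non-centrality formulation printed in
the output: attenuated effect `b = K(OR/(1+K(OR−1))−1)`, variance
`v = (K(1−K)−b²)/(N·R²)`, `NCP = b²/v`, power = upper tail of a
non-central chi-square(1, NCP) beyond the central 1−α quantile. At
OR = 1 the function returns α exactly. The formula is asymmetric in
OR vs 1/OR (the attenuation is not log-symmetric); power is monotone in
N, R² and in effect magnitude within each branch.

# The synthetic-data generators

`simulateLDReference` builds block-diagonal LD: r² is exactly zero
across blocks, `withinBlockR2 · decay^(|i−j|−1)` within (decay = 1
gives constant within-block r²; per-variant LD scores are 1 + the block
row sum). Blocks sit 20 Mb apart so cross-block pairs are also outside
any clumping window.

`simulateMRSumstats` draws, per variant: maf ~ U(mafRange); true
exposure effects with half-normal magnitudes rescaled so
`sum(2·maf(1−maf)·gamma²)` equals `exposureR2Total` exactly. The
half-normal (all-positive) orientation models the GWAS convention of
reporting instruments for the exposure-increasing allele; it matters
because with sign-symmetric instrument effects, directional pleiotropy
cancels out of ratio-based estimators by symmetry and bias-ordering
experiments would compare noise. Exposure sampling noise uses
`se = 1/sqrt(2·maf(1−maf)·n)`, the inversion of the R² formula, which
keeps the R²/F arithmetic self-consistent; binary outcomes scale se by
`1/sqrt(K(1−K))` with K the outcome case fraction (a config field,
default 0.5 — a balanced case-control design). Outcome effects are
`causalBeta·gamma` plus pleiotropy on a `propInvalid` subset: balanced
(zero-mean normal), directional (nonzero mean), or correlated
(proportional to instrument strength, violating InSIDE). Instruments
are LD-independent — one per block — unless correlated variants are
requested explicitly, which keeps estimator tests independent of
clumping tests. Default scales mirror a urate-to-neuropathy style
study: 89 instruments, R² = 7.92%, n = 288,649 / 274,660, true
OR = 1.17.

`simulateLDSCZscores` draws bivariate normal z pairs with
`Var(z) = 1 + n·h²·l/m` and covariance
`rg·sqrt(h²₁h²₂)·sqrt(n1·n2)·l/m + n_overlap·rho/sqrt(n1·n2)`; the
phenotypic correlation rho inside the overlapping subsample is taken
equal to rg, a single-parameter simplification adequate for testing
that the intercept absorbs overlap. LD scores are 1 + Gamma(2, 15),
giving a realistic mean near 30. Defaults: h² = 9.64% and 1.05%,
rg = 0.293, m = 20,000 — m is a desk-scale variant count at which the
jackknife is already well behaved.

What the generators deliberately do not emulate: linkage between
instruments and non-instrument variants, allele-frequency differences
between the two GWAS populations, strand errors, winner's-curse
selection of instruments, population stratification, and case-control
ascertainment beyond the K(1−K) variance scaling. Passing tests
therefore demonstrate correctness of the estimators and their
calibration under the stated model, not robustness to those real-data
pathologies.

# Simulation budgets and numerical choices

Monte-Carlo budgets are chosen for workstation-scale runs: 500
replicates for parameter-recovery checks, 2,000 for type-I error, 200
for MR-PRESSO calibration and Steiger direction, bootstrap default
1,000. Every generator is a pure function of (config, seed); every
report records its seed; rerunning a pipeline with the same config and
seed reproduces the report bundle byte for byte (no timestamps are
written). Degenerate inputs are handled explicitly rather than left to
numerics: zero exposure effects make Wald ratios undefined (error),
all-equal ratios short-circuit the mode bandwidth (which would
otherwise be zero), Q ≤ df yields I² = 0, and empty instrument sets
name the stage that emptied them.

# Known limitations

No MR-RAPS, debiased IVW, CAUSE, Radial-MR, MVMR-Egger or
constrained-intercept LDSC — the method set is intentionally the named
battery above. The LD reference is supplied or simulated, never
computed from genotype panels. The first-order Wald variance ignores
exposure-side noise, adequate for strong instruments (F well above 10)
but optimistic near the threshold. The jackknife slightly
underestimates the rg ratio's spread when the smaller heritability is
near zero. The Steiger observed-scale approximation for binary
outcomes is one of several reasonable scale choices; borderline
variants can flip under a liability-scale convention.
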
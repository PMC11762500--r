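---
title: "Methods: alcohol EpiScores and mixture-model EWAS on blood DNAm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: alcohol EpiScores and mixture-model EWAS on blood DNAm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Self-reported weekly alcohol consumption is a noisy phenotype: people
misremember, under-report, and a single week's intake can deviate from the
habitual pattern that actually drives physiology. Blood DNA methylation
(DNAm) integrates exposure over time, so a weighted sum of CpG methylation
values — an *EpiScore* — can serve as a more stable index of habitual
intake. This package implements the two analytical arms of that idea on
synthetic cohorts with known ground truth:

1. **Prediction**: elastic-net EpiScores of log-transformed weekly units,
   trained under a grid of designs (feature pre-selection vs the full
   methylome; everyone vs "normal-week" reporters only; sex-specific
   designs), projected into held-out data and evaluated by Pearson
   correlation and incremental R² over an age + sex model.
2. **Inference**: a Bayesian mixture-prior regression (BayesR-style) fit
   jointly over all CpGs, yielding per-CpG posterior inclusion
   probabilities (PIP) for an epigenome-wide association study and a
   variance-components estimate of how much of the phenotype the whole
   methylome explains.

Real cohorts of this kind are access-restricted, so a first-class
synthetic-data module emulates their statistical structure; every claim the
package makes is tested against the generator's known truth or against
independent oracles.

## The phenotype layer

Units per week (one NHS unit = 8 g / 10 ml ethanol) enter all models as
`log(units + 1)` (natural log; `log_units()`). Zero units maps to zero and
the metrics used downstream (r, R²) are invariant to the log base.
Drinker categories use the conventional sex-specific moderate/heavy
thresholds of 14 (F) and 21 (M) units/week; the boundary is inclusive
("14 and over"), a convention we fix and test because the thresholds alone
do not determine it. `residualize()` is plain least squares with an
intercept; rank-deficient covariate designs raise an error naming the
collinear columns rather than silently pivoting them away.

## The synthetic cohort generator

`simulate_methylome()` draws each CpG's beta values from a Beta
distribution around a CpG-specific mean in one of three methylation state
classes (low / intermediate / high), then adds structure on the logit (M-value)
scale so values stay strictly inside (0, 1):

* **Batch shifts**: per batch × CpG, with sd `batch_sd` (default 0.25)
  *times the CpG's base logit-scale sd*.
* **Latent cell-composition-like factors**: `n_latent` factors loading on
  a sparse susceptible subset (`latent_frac`, default 15% of CpGs) with
  loadings of `latent_sd` (default 0.5) times the CpG's base sd.

Expressing this structure relative to each CpG's own variability matters:
absolute-scale shifts would dominate the narrow logit-scale variance of
typical CpGs and induce genome-wide inter-CpG correlations far stronger
than anything seen in population blood methylation data, which in turn
destabilizes any joint model across CpGs. With the relative scaling, most
CpG pairs are near-uncorrelated and the susceptible subset is moderately
correlated — the regime the joint EWAS model is designed for.

`simulate_phenotype()` builds habitual log-intake on a standardized scale as

```
h_std = covariates + sum_j beta_j * z(M_j) + noise
```

with a three-tier sparse effect architecture (`effect_architecture()`):
counts of small/medium/large causal CpGs at per-CpG variance fractions
1e-4 / 1e-3 / 1e-2 — deliberately the same three effect-size classes the
mixture prior assumes. Noise is scaled so the methylome explains exactly
the architecture's target fraction of variance. Habitual units are
`exp(h) - 1`, floored at zero, with location/scale (2.1, 0.9 on the log
scale) chosen to give a right-skewed distribution with a mean near 11
units/week, matching large population cohorts. Covariate effects (age
−0.05, male +0.30, smoking +0.15 on the standardized log scale) are
realistic-magnitude choices; male sex is the dominant covariate, as in
population data.

**Reporting model.** The questionnaire asks about *last week*; the
methylome tracks *habitual* intake. `reporting_model()` assigns each
participant a state — normal week (62.8%), more than normal (22.5%), less
than normal (9.7%), unknown (remainder; frequencies follow a large
population cohort) — and perturbs deviant reporters' units multiplicatively
on the `units + 1` scale: up by `exp(|N(0, deviation_sd)|)` for "more",
down by the reciprocal for "less", floored at 0 units. Acting on
`units + 1` makes the deviation exactly additive on the `log(units + 1)`
modelling scale, so both directions attenuate predictor performance
symmetrically; a deviation acting on raw units would be swallowed by the
`log1p` compression for light drinkers and barely touch "less" reporters.
The default `deviation_sd = 1` (median ~2× deviation) is chosen so the
designed monotonicity — predictors perform best in normal-week reporters —
is realized at realistic stratum sizes; with much smaller deviations the
three strata are statistically indistinguishable at any feasible cohort
size, which would defeat the purpose of the mechanism.

What the generator does **not** emulate: probe-level technical artifacts
(detection failures, cross-hybridization), kinship/pedigree structure,
fine-grained cell-count deconvolution, genuine genomic autocorrelation
along the chromosome, and zero-inflation of units beyond what the
log-normal floor produces (~1–2% non-drinkers rather than the ~19% of real
cohorts). Passing tests therefore demonstrate correctness of the methods
under the stated statistical structure, not performance on raw array data.

## EpiScore training, projection and evaluation

Training standardizes CpG beta values to mean zero and unit variance (so
weights are standardized effect sizes) and fits an elastic net with mixing
parameter α = 0.5 over a λ path, selecting λ at the minimum mean
10-fold cross-validated squared error; fold assignment is seeded. Ties on
the CV curve break toward the smallest λ (the densest of the tied models).
Zero-variance CpGs are dropped with a warning before standardization,
which would otherwise be undefined. An empty selected model is legal and
projects to a constant score.

Projection standardizes CpG values *within the target cohort* by default
(`standardize = "target"`); reusing the training means/sds is available as
`standardize = "training"`. Target standardization makes the score
invariant to cohort-level location/scale differences (e.g. platform
shifts) at the cost of assuming comparable within-cohort variation.

`evaluate()` reports Pearson r against `log(units + 1)`, the incremental
R² (in percentage points) of adding the score to an age + sex linear
model, and the two-sided marginal p of the score coefficient. The
incremental R² equals the squared semipartial correlation of the score
with the outcome given age and sex — an algebraic identity the test suite
checks to 1e−8.

`design_grid()` trains one model per (feature set × training
subpopulation) cell and evaluates each on the full test set and within
each normal-week-flag stratum; unknown-flag samples stay in the "all"
evaluation and are excluded from flag strata. `sex_specific_designs()`
matches training sizes to `min(n_F, n_M)`, builds female, male and 50/50
mixed training sets, and cross-tests all three per sex.

Train/test hygiene is enforced structurally (training never sees test
data) and verified by a mutation test: perturbing the test set leaves the
trained model bit-identical.

## The mixture-prior EWAS model

The sampler fits, on covariate-residualized and standardized M-values `X`
and the covariate-residualized phenotype `y` (scaled internally to unit
variance):

```
y = X beta + e,   e ~ N(0, sigma2)
beta_j ~ pi0 * delta0 + sum_k pik * N(0, gamma_k)
```

with `gamma = (1e-4, 1e-3, 1e-2)` by default — slab variances that are
literal fractions of phenotypic variance, i.e. the three components
correspond to CpGs explaining 0.01%, 0.1% and 1% of the phenotype.
Updates are single-site conjugate Gibbs steps with residual-vector
maintenance, giving O(n) cost per CpG per sweep; the per-sweep update
order is a seeded random permutation keyed to CpG identifiers (columns are
sorted by name internally), which makes the entire posterior equivariant
under permutation of input columns — a property the tests assert exactly.

Numerical/design choices that the model class leaves open:

* **Mixture proportions** are *collapsed out* of the membership updates
  (Dirichlet-multinomial urn weights `alpha + n_k` over the other CpGs'
  memberships) rather than conditioned on a sampled `pi` vector. When a
  slab variance is small enough that spike and slab are per-CpG
  indistinguishable (`n * gamma_k` well below 1), conditioning on `pi`
  leaves the proportions in a marginally stable random walk that mixes far
  too slowly at moderate p and erratically inflates null variance
  estimates; collapsing removes the walk. `pi` is still drawn each sweep
  from its conditional for reporting and diagnostics.
* **Dirichlet concentration** defaults to 0.5 (mildly sparsity-favoring)
  for the same reason: the likelihood cannot supply a drift toward the
  spike for indistinguishable components, so the prior must.
* **Residual variance** carries a scaled-inverse-χ² prior with ν₀ = 2 and
  s₀² = var(y)/2 — weakly informative, and `sigma2 > 0` by construction.
* **Chain accounting**: the conventional settings for this model class are
  a burn-in of 5000 sweeps, 10,000 retained draws and thinning by 5; we
  summarize over the most recent 1000 stored draws by default. Stored
  draws (`draws_retained / thin`) and the summarized count
  (`used_iterations`) are deliberately independent knobs because the
  convention fixes both numbers without forcing them to agree.
* **Oracle hooks**: `fix_sigma2` and `fix_pi` freeze those updates so the
  sampler can be compared exactly against closed forms (the conjugate
  ridge posterior at p = 1; exhaustive 2^p Bayesian model averaging at
  p ≤ 5). The test suite performs both comparisons within Monte-Carlo
  error.

Posterior summaries follow the standard conventions: PIP is the fraction
of used draws in which a CpG occupies any nonzero component ("any
nonzero" is our reading of mixture membership; occupancy per component is
also reported and sums to one per CpG); the per-iteration variance
explained is the sum of squared standardized effect draws, summarized by
its mean and equal-tailed 95% credible interval; lead CpGs are those with
PIP *strictly above* 0.95. Convergence is monitored with a Geweke test
(first 10% vs last 50% of a scalar chain, batch-means spectral variance
with batch size ≈ √segment length) plus a lag-k autocorrelation table; a
constant chain is defined to have z = 0 with a warning.

## Association battery

Linear (standardized β), logistic (OR per SD), Cox (HR per SD) and
brain-volume models (standardized β adjusting for intracranial volume),
each adjusting for age and sex, with Wald 95% CIs throughout —
conventional for OR/HR reporting with symmetric log-scale intervals.
Exposures are standardized internally, so all per-SD effects and p-values
are invariant to positive rescaling of the exposure (tested). Perfect
separation in the logistic model raises an error rather than returning a
boundary estimate. The BH-FDR family is all outcomes × both exposures
within one cohort; whether exposures should instead be corrected
separately is a genuinely open convention, and the joint family is the
more conservative default.

## Problem sizes used by the test suite

The property checks run at sizes chosen to finish on a single desktop CPU
while keeping each property resolvable: variance-component recovery, null
calibration and PIP detection at n = 2000 × p = 2000 (burn-in 500, 1000
used draws, thin 1); EpiScore recovery at n = 5000 (3000 train / 2000
test) × p = 5000 with 200 causal CpGs; the reporting-monotonicity check at
n = 6000 × p = 2000 so the "less" stratum (~10% of the test set) retains
enough samples for a stable correlation. The variance-component and
detection simulations use a no-deviation reporting model so that the
planted methylome variance applies to the *observed* phenotype; the
reporting mechanism is exercised separately by the monotonicity check,
where its attenuation is the very thing under test.

For the EpiScore-recovery check, the 200 causal CpGs are split 160
small-tier / 40 large-tier: comparing an achieved test-set R² against the
planted predictable fraction is only meaningful when the planted signal is
estimable at the training size, and effects explaining ~0.1% of variance
are individually indistinguishable from noise at n = 3000 for any
estimator, which would turn the comparison into a test of an information
bound rather than of the pipeline.

## Known limitations

* PIP-based detection of CpGs explaining exactly 1% of variance at
  n = 2000 sits at the posterior's own decision boundary (the required
  realized marginal association is ≈ the planted non-centrality), so
  per-CpG detection probability is ~0.75 there, with realized-association
  sampling noise — not sampler error — deciding individual calls. Larger n
  or larger effects move detection off the boundary.
* The variance-explained summary Σβ² ignores correlation between included
  CpGs; under strong inter-CpG correlation it is not identical to the
  realized R² of the true generating score.
* Single chain by default, as is conventional for this model class;
  the Geweke diagnostic and the autocorrelation table are the in-package
  convergence checks.
* The generator's omissions listed above mean external validity on raw
  Illumina data is out of scope.
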
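# alcoscore

Blood DNA methylation (DNAm) analysis of alcohol consumption: elastic-net
**EpiScores** (methylation risk scores) of self-reported weekly alcohol
units, and a from-scratch Bayesian mixture-prior regression (BayesR-style
Gibbs sampler) for joint-conditional **EWAS** and **methylome variance
partitioning** — exercised end-to-end on seeded synthetic cohorts with
known ground truth.

## Who this is for

Epigenetics researchers who want a tested, reusable implementation of the
two standard analytical arms of DNAm biomarker studies of alcohol:

1. **Prediction** — train an EpiScore on `log(units/week + 1)` by elastic
   net (α = 0.5, 10-fold CV selecting λ at minimum mean CV error) with
   CpG values standardized to mean 0 / unit variance, under a design grid:
   feature pre-selection (prior-EWAS CpG panels, 450K-array intersection)
   × training subpopulation (everyone vs "normal week" reporters) × sex-
   specific designs. Project scores into held-out cohorts (target-cohort
   standardization) and evaluate by Pearson *r* and incremental *R²* over
   an age + sex model.
2. **Inference** — fit, jointly over all CpGs,

   ```
   y = X beta + e,   beta_j ~ pi0*delta0 + pi1*N(0,1e-4) + pi2*N(0,1e-3) + pi3*N(0,1e-2)
   ```

   on covariate-residualized, standardized M-values, by single-site
   conjugate Gibbs sampling (mixture proportions collapsed out;
   O(n) per CpG per sweep in Rcpp). Slab variances are literal fractions
   of phenotypic variance — the components correspond to CpGs explaining
   0.01%, 0.1% and 1% of the phenotype. Outputs: per-CpG posterior mean
   effect, SE, posterior inclusion probability (PIP; lead CpGs at
   PIP > 0.95), mixture occupancy, and the methylome variance-explained
   posterior (mean + 95% credible interval), with Geweke convergence
   diagnostics.

Real cohorts of this kind are access-restricted, so the package ships a
first-class synthetic-cohort generator (`simulate_methylome()`,
`simulate_phenotype()`) emulating their statistical structure: bimodal
beta-value distributions, batch effects, latent cell-composition-like
factors, sparse three-tier CpG effect architectures, age/sex/smoking
confounding, and a reporting model in which the methylome tracks
*habitual* intake while the questionnaire reports *last week's* intake.

## Worked example

```r
library(alcoscore)

## simulate a cohort: 2,400 people, 1,500 CpGs, 2 batches
methyl <- simulate_methylome(2400, 1500, n_batches = 2, seed = 42)
cohort <- simulate_phenotype(methyl, effect_architecture(), seed = 42)
print(cohort)
#> Synthetic DNAm cohort: 2400 samples x 1500 CpGs
#>   causal CpGs: 680 | target methylome variance: 0.5 | realized: 0.512
#>   reporting flags: normal=1539, more=517, less=233, unknown=111

## split, pre-select a causal-enriched CpG panel, train, project, evaluate
split <- split_cohort(cohort, c(train = 0.52, test = 0.48), seed = 42)
set.seed(42)
panel <- sort(c(cohort$truth$causal,
                sample(setdiff(colnames(methyl), cohort$truth$causal), 150)))
model <- train_elastic_net(preselect_features(split$train$methyl, panel),
                           log_units(split$train$cohort$units), seed = 42)
print(model)
#> EpiScore model: 139 of 830 CpGs selected (alpha = 0.5 , lambda = 0.07848 )
#>   trained on n = 1248 | subset: everyone | features: all
score <- project(model, split$test$methyl)
evaluate(score, split$test$cohort$units,
         split$test$cohort$age, split$test$cohort$sex)
#>   subset_label    n pearson_r incremental_r2   marginal_p
#> 1          all 1152 0.4272536        17.4597 1.460752e-57

## joint-conditional EWAS + variance partitioning on the full cohort
post <- bayesr_ewas(m_values(methyl), cohort$cohort$units, cohort$cohort$age,
                    cohort$cohort$sex, cohort$cohort$smoking,
                    batch = cohort$cohort$batch,
                    config = bayesr_config(burn_in = 500, draws_retained = 1000,
                                           thin = 1, used_iterations = 1000,
                                           seed = 42))
print(post)
#> Mixture-model EWAS posterior: 1500 CpGs, 1000 used iterations
#>   variance explained: 34.3% (95% CrI 29.6%, 39.2%)
#>   lead CpGs (PIP > 0.95 ): 23
head(call_significant(post), 3)
#>           cpg   mean_beta         se pip
#> 132 cg0000132 -0.14739532 0.01805398   1
#> 528 cg0000528 -0.08083786 0.01944896   1
#> 529 cg0000529  0.09366811 0.01985071   1
```

Reading the output: the EpiScore correlates *r* = 0.43 with held-out
self-reported consumption and adds 17.5 percentage points of *R²* beyond
age and sex. The EWAS attributes 34% of the *reported* phenotype's
variance to the methylome — lower than the planted 50% of *habitual*
intake because a quarter of the cohort reported a week that deviated from
their habit; that attenuation is exactly the mechanism the reporting model
encodes, and scores evaluate best in the normal-week stratum
(`design_grid()` tabulates this).

A full pipeline driver (`run_pipeline(default_run_config())`) chains
simulation, phenotype preparation, the EpiScore design grid, the EWAS and
a phenome association battery (linear / logistic / Cox / brain-volume
models with BH-FDR), writing per-stage tables, a run log and a
deterministic `summary.json`.

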
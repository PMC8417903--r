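# latentcog

Two-stage stratification of pre-dementia longitudinal cohorts, for
biostatisticians modelling early Alzheimer's disease:

1. **Latent clinical phenotypes.** A multivariate latent-class linear mixed
   effects model summarises each participant's repeated CDR Sum of Boxes
   and MMSE scores. A scalar latent process drives both outcomes through
   linear links `Y_k = η₁ₖ + η₂ₖ(Λ + ε)`, with
   `Λ_i(t) | class g = xᵀβ + γ₀g + γ₁g t + u_i`, a class-specific random
   intercept `u_i ~ N(0, ω_g)`, and a multinomial-logistic membership
   model. The number of classes is chosen by BIC and relative entropy;
   participants are hard-assigned by posterior class membership.
2. **Neuropathological endotypes.** Bayesian profile regression — a
   Dirichlet-process mixture over the assigned class, five binary CSF and
   radiological flags, and a 4-dimensional Gaussian block of volumetric
   measures — clusters participants into biomarker-profile endotypes
   linked to the clinical phenotypes. Chains are summarised through
   posterior similarity matrices, PAM representative clusterings with
   silhouette-selected cluster counts, and multi-chain consensus.

A split-half stability framework (Cohen's kappa, adjusted Rand index,
similarity-matrix correlations, held-out prediction) and a synthetic cohort
generator with known ground truth make every stage testable end to end.
See the vignette in `vignettes/two-stage-stratification.Rmd` for the models
and design decisions.

## Worked example

Generate a crisp two-class synthetic cohort, derive the model inputs, and
fit the two-class mixed model:

```r
library(latentcog)

sim    <- generate_cohort(synth_scenario("crisp_classes", n_subjects = 300), seed = 1)
cohort <- filter_eligible(sim$cohort, require_apoe = TRUE)
d      <- prepare_mlcmm_data(cohort)
fit    <- fit_mlcmm(d$outcomes, d$covariates, mlcmm_spec(2),
                    mlcmm_control(n_starts = 3, seed = 1))
fit
#> <mlcmm_fit> G = 2 classes, N = 300 subjects, 17 free parameters
#>   log-likelihood -4144.33 | BIC 8385.63 | relative entropy 0.991
#>   class sizes: 219, 81
```

The relative entropy of 0.991 says the posterior classification is almost
crisp; the class sizes track the generating membership probabilities
(logits 0.85 vs 0: about 70/30). Hard assignments recover the true classes
at adjusted Rand index 0.97:

```r
adjusted_rand(fit$labels, sim$truth$class[match(fit$subject_ids, sim$truth$subject_id)])
#> [1] 0.9722825
tidy(fit)[1:4, ]
#> # A tibble: 4 × 5
#>   term          estimate std.error statistic  p.value
#> 1 xi_class1      0.993     0.131       7.61  2.78e-14
#> 2 beta_age      -0.00570   0.00652    -0.875 3.82e- 1
#> 3 beta_sex_male -0.0394    0.0955     -0.412 6.80e- 1
#> 4 beta_edu2      0.200     0.124       1.61  1.07e- 1
```

Stage two on a three-cluster cohort: run independent chains, check their
agreement, extract the consensus representative clustering, and summarise a
cluster-level parameter posterior:

```r
sim2   <- generate_cohort(synth_scenario("crisp_clusters", n_subjects = 200), seed = 2)
chains <- run_chains(profreg_data(sim2$profiles), n_chains = 3,
                     control = profreg_control(n_iter = 4000, burn_in = 1000,
                                               thin = 5, seed = 2))
agr <- chain_agreement(chains, k_range = 2:6)
c(agr$mean_ari, agr$mean_pearson)
#> [1] 1 1
rc <- representative_clustering(consensus_psm(agr$psm_list), 2:6)
rc
#> <representative_clustering> k = 4; sizes: 76, 69, 54, 1
adjusted_rand(rc$labels, sim2$truth$cluster[match(rc$ids, sim2$truth$subject_id)])
#> [1] 0.993904
```

The three generating clusters are recovered (ARI 0.99); the fourth
"cluster" is a single outlying subject the silhouette criterion prefers to
isolate — its wide credible interval below flags it as unstable, which is
exactly how cluster uncertainty is meant to be read:

```r
pp <- cluster_param_posteriors(chains, rc)
pp[pp$parameter == "ad_positive", ]
#> # A tibble: 4 × 5
#>   cluster parameter     mean ci_lower ci_upper
#> 1       1 ad_positive 0.922    0.867     0.965
#> 2       2 ad_positive 0.0857   0.0392    0.145
#> 3       3 ad_positive 0.125    0.0635    0.205
#> 4       4 ad_positive 0.292    0.0403    0.770
```

`plot_psm(consensus_psm(agr$psm_list), rc)` draws the co-clustering
heatmap; `autoplot(fit, scale = "cdrsb")` draws the class trajectories with
confidence bands on the CDRSB scale. `make_splits()`, `class_stability()`
and `cluster_stability()` run the stability assessment.

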
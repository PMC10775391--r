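# metapred

Stacked meta-prediction of 10-year incident coronary artery disease (CAD)
risk, with attribution-based risk subgroups and counterfactual intervention
simulation — for biostatisticians and methodologists who want a fully
testable, self-contained implementation of the two-stage ("meta-prediction")
risk-modelling idiom.

## The model

Individuals are split into a **prevalent** cohort (disease at enrolment) and
an **incident** cohort (onset within ten years of enrolment), with eligible
controls allocated proportionally so the two case rates match. Stage-1
gradient-boosted models trained on the prevalent cohort predict, for each
registered diagnosis *d* and biomarker *b*:

* baseline onset of *d* (early &lt; 55 y / late ≥ 55 y / any age), from
  **unmodifiable** features only (age, sex, ancestry, family history,
  polygenic scores) — modifiable biomarkers are excluded to avoid reverse
  causation;
* future onset of *d* within 10 and 20 years, from all features;
* the baseline value of *b*, in unmodifiable-only and all-feature flavours.

Their predictions ("meta-features") are stacked with measured features and
polygenic risk scores `PRS_i = Σ_j w_j · dosage_ij` (standardized weighted
allele sums) into the final incident-risk classifier

> P(CAD within 10 years | measured, PRS, meta),

an xgboost ensemble fitted with Saabas-attribution pre-selection,
minimal-model feature selection, adaptive hyperparameter search with early
pruning, inverse-class-frequency weights, seed-bagging, and exact prior
correction of the class-weighted probabilities back to the absolute-risk
scale. Downstream machinery clusters cases by their exact tree-SHAP
attribution vectors (Ward linkage, Euclidean distance), ranks
subgroup-distinguishing features by the one-way ANOVA effect size
η² = SS_between/SS_total, assigns controls by a multiclass classifier
(strict 0.5 probability threshold), and simulates clinical interventions
(LDL, HbA1c, SBP lowering to guideline targets, with co-modulated analytes)
by closed-loop re-inference through the frozen stage-1 models.

A synthetic biobank generator with known ground truth (discrete-time yearly
hazard with a gene-by-LDL interaction, latent mechanism subgroups,
medication effects, missingness, EHR eligibility structure) stands in for
real biobank data; every downstream claim is tested against its analytic
oracle. See the methods vignette
(`vignettes/meta-prediction-methods.Rmd`) for model details and design
rationale.

## Worked example

```r
library(metapred)

cfg <- sim_config(n_individuals = 20000, seed = 42)
res <- run_pipeline(cfg)          # a few minutes on one CPU

print(res$model)
#> Stacked 10-year incident CAD meta-prediction model
#>   n = 9292 (train 7433 / test 1859), 12 selected features (measured 7, PRS 1, meta 4)
#>   held-out AUROC 0.744 (95% CI 0.704-0.783), AUPRC 0.271
#>   Youden cutoff 0.065: F1 0.317, macro-F1 0.580

# single-family ablations: measured-only vs PRS-only vs meta-features-only
ablate_families(res$model, res$design, res$y)
#>     family n_features     auroc     auprc
#> 1     full         12 0.7443536 0.2710070
#> 2 measured         12 0.6972888 0.2385176
#> 3      prs         12 0.7125585 0.2243527
#> 4     meta         12 0.7392942 0.2645691

# counterfactual LDL lowering to 70 mg/dL in at-risk individuals,
# compared against the generator's analytic ground truth
iv <- res$interventions$ldl
round(c(mean_absolute_reduction = mean(iv$profile$absolute[iv$eligible]),
        oracle_correlation = iv$oracle_correlation), 3)
#> mean_absolute_reduction      oracle_correlation
#>                   0.072                   0.819
```

Reading the output: the stacked model discriminates held-out incident cases
(AUROC ≈ 0.74 on this replicate) and beats every single feature family,
with meta-features the strongest family — the stacked &gt; meta &gt;
measured / PRS ordering that motivates meta-prediction. The intervention
engine's predicted per-individual absolute risk reductions track the
generator's closed-form counterfactual risks (Pearson r ≈ 0.8), and the
mean reduction among eligible individuals is a few absolute percentage
points, graded by polygenic burden (`iv$rolling`).

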
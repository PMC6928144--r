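# cstload

Slice-weighted corticospinal tract lesion load, dominance analysis of tract
predictors, and stepwise prediction of upper-limb motor outcome after
stroke.

## What it does, for whom

Stroke researchers relating lesion anatomy to motor recovery need three
things done carefully: (1) a lesion-load metric that respects the funnel
shape of the corticospinal tract (CST); (2) a principled ranking of highly
intercorrelated tract predictors; (3) a small, well-diagnosed multivariable
model of six-month upper-limb impairment (Fugl-Meyer Upper Extremity,
FM-UE, 0–66). `cstload` implements all three as a tidyverse-style R
package, plus a synthetic-data module (tube-like tract templates,
ellipsoidal lesions, cohorts with a known generative model) so the whole
pipeline is testable without patient data.

The core metric weights each axial slice of the lesion–tract overlap by the
tract's narrowing. For tract X with per-slice area m(x) and maximal slice
area m(x\*), a lesion with n(x) voxels inside the tract at slice x scores

    w-X-LL = Σ_x n(x) · m(x*) / m(x)

in dimensionless weighted voxels. Damage where the tract squeezes through
the posterior limb of the internal capsule counts for more than the same
voxel count in the corona radiata. The metric is computed for six CST
sub-pathways (by cortical origin: M1, PMD, PMV, SMA, preSMA, S1) and their
union ("SMATT", the whole-CST template).

Relative importance of the seven load predictors uses dominance analysis:
OLS R² over all 2⁷ predictor subsets, additional R² contributions by model
size, the complete/conditional/general dominance hierarchy, and a
case-resampling bootstrap that reports how reproducibly each pairwise
designation survives resampling. The dominant tract load then joins
one-week FM-UE and an age ≥ 70 indicator in a stepwise (probability-of-F
0.05/0.10) regression with the standard diagnostic battery
(multicollinearity, casewise outliers, residual normality via
Kolmogorov–Smirnov, Durbin–Watson, homoscedasticity plot data), a
1000-resample coefficient bootstrap, and adjusted-R² shrinkage as a
cross-validation index.

## Worked example

A complete synthetic analysis of a 27-subject cohort:

```r
library(cstload)
cfg <- run_config("demo-out", seed = 27, n_subjects = 27,
                  B_dominance = 1000, B_coef = 1000)
res <- run_full(cfg)
res$stepwise
#> <stepwise_fit> outcome fmue_m6; final model: fmue_wk1 + w_PMV_LL
#>  step        predictors     r r_squared adj_r_squared r2_change p_change  see
#>     1          fmue_wk1 0.806     0.650         0.636     0.650 3.87e-07 8.13
#>     2 fmue_wk1+w_PMV_LL 0.869     0.755         0.735     0.106 3.67e-03 6.94
res$dominance
#> <dominance> general weights (sum = full-model R^2):
#>    w_PMV_LL     w_M1_LL  w_SMATT_LL     w_S1_LL    w_PMD_LL w_preSMA_LL
#>      0.0499      0.0464      0.0322      0.0173      0.0156      0.0122
#>    w_SMA_LL
#>      0.0105
res$diagnostics
#> <model_diagnostics> max |r| between predictors: 0.112; outliers
#> (|std resid| > 3): 0; KS normal p = 0.841; Durbin-Watson d = 2.542
#> (row order); shrinkage = 0.020
```

Reading this: week-1 FM-UE alone explains 65% of six-month variance
(SEE 8.1 FM-UE points); adding the ventral-premotor lesion load lifts R² to
0.755 (change p = 0.004), and at n = 27 the dichotomized age indicator does
not pass the 0.05 entry threshold. The general dominance weights sum to the
full seven-predictor R², and which premotor tract ranks first is exactly
the kind of small-sample question the reproducibility table
(`reproducibility_range(res$reproducibility)`) is there to answer — at this
cohort size the pairwise general-dominance reproducibilities span roughly
0.4–0.9, so the ranking should be read with care. Diagnostics show no
collinearity flag (max |r| = 0.11 between final predictors), no casewise
outliers, unremarkable KS and Durbin–Watson values, and 2% shrinkage.

`run_full()` writes every table a report needs (correlation matrix with
Munro labels, dominance curves data, reproducibility, stepwise steps,
bootstrap CIs, diagnostics JSON, age-grouped scatter data, lesion overlay
NIfTI) under the output directory, plus a manifest that reproduces the run:
same config + seed ⇒ byte-identical numeric outputs.

Lower-level entry points mirror the analysis stages:
`read_mask()` / `write_mask()` / `read_tract_atlas()`,
`weighted_lesion_load()`, `lesion_load_table()`, `correlation_matrix()`,
`univariate_screen()`, `all_subsets_r2()`, `dominance_stats()`,
`bootstrap_reproducibility()`, `stepwise_regression()`,
`model_diagnostics()`, `bootstrap_coefficients()`; `tidy()`/`glance()`
methods and `autoplot()`/`plot_age_grouping()` figures cover the result
objects. The methods vignette
(`vignettes/weighted-lesion-load.Rmd`) documents the model, parameter
defaults, and design decisions.

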
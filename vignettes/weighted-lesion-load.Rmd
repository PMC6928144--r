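---
title: "Slice-weighted corticospinal lesion load and dominance-based outcome modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slice-weighted corticospinal lesion load and dominance-based outcome modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(cstload)
library(dplyr)
```

## The problem

After an ischaemic stroke, the best early predictors of upper-limb motor
recovery combine clinical scores with measures of how much the lesion
disrupts the descending motor pathways. The corticospinal tract (CST) is not
one cable: fibres descend from the primary motor cortex (M1), dorsal and
ventral premotor cortex (PMD, PMV), supplementary and pre-supplementary
motor areas (SMA, preSMA), and primary somatosensory cortex (S1), and these
sub-pathways can be segmented on a common template. `cstload` quantifies
lesion encroachment on each sub-pathway, asks which sub-pathway matters most
for six-month upper-limb impairment (Fugl-Meyer Upper Extremity, FM-UE,
integer 0–66, higher = less impaired), and builds a compact multivariable
prediction model.

## Slice-weighted lesion load

A raw lesion–tract overlap count treats every voxel alike, but the pyramidal
tract funnels: a handful of damaged voxels at the posterior limb of the
internal capsule, where the whole tract squeezes through a few voxels per
axial slice, is far more consequential than the same count up in the corona
radiata. The weighted lesion load corrects for this geometry slice by slice.
For a tract X with per-slice area $m(x)$ (voxels in axial slice $x$) and
maximal slice area $m(x^*)$, a lesion with $n(x)$ voxels inside the tract at
slice $x$ scores

$$\mathrm{w\text{-}X\text{-}LL} = \sum_x n(x)\,\frac{m(x^*)}{m(x)},$$

in dimensionless "weighted voxels". Slices where the tract is absent have
$n(x) = 0$ by construction, so no division by zero can occur; slices where
the tract is present but unlesioned contribute zero. The weighted load is
always at least the raw overlap, with equality exactly when all overlap sits
on maximal slices. It is additive over disjoint lesions and invariant under
whole-voxel translations of lesion and tract together — properties the test
suite checks against an independent per-voxel oracle
$\sum_{v \in L \cap X} m(x^*)/m(z(v))$.

The whole-CST predictor ("SMATT", after the sensorimotor area tract
template) is the voxelwise union of the six sub-tracts, profiled and
weighted like any tract. Using the union's own slice profile (rather than
summing sub-tract loads) was a genuine design choice: the union is a tract
in its own right, and its profile — not the sum of overlapping members —
describes its narrowing.

### Hemisphere policy

Published lesion-load pipelines differ on whether lesions are scored against
the ipsilesional template or mirrored onto a canonical hemisphere first.
Both conventions exist in the literature, so the choice is explicit: the
default `"ipsilesional"` policy scores each subject against the tracts of
the affected hemisphere recorded in the cohort table, and the `"flip"`
policy mirrors every lesion onto a canonical hemisphere with `flip_lr()`
(an involution about the grid's midsagittal plane) before scoring. The
policy used is recorded in every output row.

## Association statistics

Cross-sectional associations between one-week FM-UE and the seven weighted
loads use Spearman rank correlation (mid-rank ties), with a two-tailed
p-value from the $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ approximation on $n-2$
degrees of freedom — the convention of mainstream statistical software at
cohort-scale n, and the default here because the asymptotic and exact
methods are indistinguishable at n in the twenties. An exact permutation
option exists for $n \le 10$. Magnitudes are labelled with Munro's
descriptive bands (0–0.25 little/none, 0.26–0.49 low, 0.50–0.69 moderate,
0.70–0.89 high, 0.90–1 very high); the 0.49/0.50 boundary is pinned by the
convention that $|\rho| = 0.48$ reads "low" while $0.53$ reads "moderate".
The bands are config-overridable. Missing data are handled by
pairwise-complete deletion with dropped counts reported. No multiple-testing
correction is applied; the two-tailed significance level is 0.05 throughout.

## Dominance analysis

The seven load predictors are strongly intercorrelated, so single
regressions cannot rank their importance. Dominance analysis ranks them by
additional explained variance over *every* context: with $p$ predictors,
the OLS $R^2$ of all $2^p$ subsets is computed (exhaustively — $2^7 = 128$
models is trivial), and the additional contribution of predictor $i$ over
subset $S \not\ni i$ is $\Delta R^2(i\,|\,S) = R^2(S \cup \{i\}) - R^2(S)$.

* **Complete dominance** of $i$ over $j$: $\Delta R^2(i|S) > \Delta R^2(j|S)$
  for every $S \subseteq P \setminus \{i, j\}$ — strict inequality over all
  subsets, the conservative Azen–Budescu convention; any tie leaves the
  relation undetermined rather than assigning a direction.
* **Conditional dominance**: $i$'s mean contribution at every model size
  $k = 0, \dots, p-1$ exceeds $j$'s.
* **General dominance**: $i$'s general weight (the grand mean of its size
  averages) exceeds $j$'s. General weights sum exactly to the full-model
  $R^2$ — the identity the tests enforce to $10^{-9}$.

Complete implies conditional implies general; the implication is asserted by
exhaustive enumeration on random instances. $\Delta R^2$ values within
$-10^{-10}$ of zero are clipped to zero before comparison as a
floating-point guard. Subset $R^2$ values come from one linear solve of the
centred cross-product system per subset; a rank-deficient subset falls back
to the SVD pseudo-solution and is flagged. An independent oracle that refits
every subset with `stats::lm()` backs the implementation in the tests.

### Bootstrap reproducibility

A dominance ordering found in one small cohort may not survive resampling.
`bootstrap_reproducibility()` draws B case resamples with replacement
(default 1000), recomputes all designations, and reports per pair and level
the fraction of resamples reproducing the original sample's designation.
Resamples in which a predictor or the outcome collapses to a constant are
redrawn (up to 100 times, then counted as non-reproducing and logged) — the
redraw policy is explicit because it is not standardized anywhere. The
per-predictor "reproducibility range" is the min–max of its pairwise
general-dominance reproducibility values. With a fixed seed the whole
procedure is bit-reproducible.

One caveat worth stating plainly: reproducibility is a *conditional*
quantity. Resamples are drawn from the observed sample, so their dominance
directions centre on the observed direction, not on the population truth;
for genuinely exchangeable predictors the reproducibility of the (random)
observed direction is typically well above one half and varies widely from
sample to sample. Reproducibility quantifies the stability of a finding
within the sample at hand, not a frequentist error rate over fresh cohorts.

## The outcome model

The dominant neuroimaging predictor joins the two established clinical
predictors — one-week FM-UE and age, entered as the indicator
$\mathbf{1}[\text{age} \ge 70]$ (the published convention places 70 itself
in the older group; the cut is configurable) — in a stepwise multivariable
OLS. Entry/removal use the classic probability-of-F thresholds 0.05/0.10,
the long-standing defaults of the commercial package that popularized
stepwise output tables; they are exposed as arguments. Each step records
$R = \sqrt{R^2}$, $R^2$, adjusted
$R^2 = 1 - (1-R^2)\frac{n-1}{n-k-1}$, the $R^2$-change with its partial-F
p-value, and the SEE (residual SD). The final model reports coefficients
with two-tailed p-values and each predictor's squared semipartial
correlation $R^2(\text{full}) - R^2(\text{full} \setminus \text{pred})$,
which coincides (to $10^{-12}$, tested) with the dominance module's
additional contribution over the remaining predictors.

Diagnostics follow the standard battery: pairwise predictor correlations
with a flag at $|r| \ge 0.9$; casewise standardized residuals
(residual/SEE) flagged beyond $\pm 3$; homoscedasticity delivered as
plot-ready (standardized prediction, studentized residual) pairs — a visual
check, deliberately not replaced by a numeric test; Kolmogorov–Smirnov on
standardized residuals against a fully specified N(0,1), with a
Lilliefors-corrected option since the uncorrected test is conservative when
parameters are estimated; and Durbin–Watson
$d = \sum_t (e_t - e_{t-1})^2 / \sum_t e_t^2$. Cross-sectional data make
$d$ order-dependent; the case order used (cohort row order by default) is
recorded in the report rather than hidden. Coefficient stability uses a
case-resampling bootstrap (1000 resamples, percentile 95% intervals), and
shrinkage $R^2 - R^2_{\text{adj}}$ serves as the cross-validation index.

## The synthetic test-bed

No patient data ship with the package; every downstream stage is exercised
on synthetic data whose statistical structure matches what the analysis
assumes.

* **Tracts** are tubes of per-slice discs on a 64×64×40 grid at 2 mm
  isotropic resolution — small enough for seconds-scale tests, large enough
  for six distinct tracts per hemisphere. Each tract descends from a
  distinct cortical origin toward a shared point near the posterior limb of
  the internal capsule, its radius shrinking linearly (cortical ~4 voxels to
  capsular ~1.5), so neighbouring tracts overlap slightly on the lower
  slices as the real template does.
* **Lesions** are ellipsoids with uniform 2–6-voxel semi-axes, centred with
  Gaussian jitter around the capsular portion of the bundle — the
  middle-cerebral-artery territory where most such lesions cluster.
* **The cohort** draws age from Normal(68, 10) truncated to 30–95 years,
  affected hemisphere right with probability 0.7, one-week FM-UE as
  $66 \cdot \mathrm{Beta}(0.6, 0.8)$ rounded (a wide, left-heavy severity
  mix), NIHSS as Poisson(9) capped at 42, and sets
  $$\mathrm{FM}_{6m} = \beta_0 + \beta_{fm}\,\mathrm{FM}_{1w}
    + \beta_{ll}\,\mathrm{wPMDLL} + \beta_{age}\,\mathbf{1}[\text{age}\ge70]
    + \varepsilon, \qquad \varepsilon \sim N(0, \sigma^2),$$
  rounded and clamped to the integer 0–66 instrument scale. Defaults
  ($\beta_0 = 10$, $\beta_{fm} = 0.75$, $\beta_{ll} = -0.08$,
  $\beta_{age} = -6$, $\sigma = 6$, n = 27) give a cohort whose outcome
  spread, ceiling behaviour, and three-predictor structure resemble a
  realistic stroke cohort. The "true" PMD load inside the generative model
  is computed with the same scorer the pipeline uses, so stored and
  recomputed loads agree exactly (a tested invariant).

Each subject's draws come from a substream derived from the master seed by
a fixed counter, so subject i is reproducible regardless of cohort size.

What the generator does *not* emulate: vascular-territory lesion shapes,
joint NIHSS–FM-UE structure (NIHSS is an independent draw), and any
dependence of week-1 FM-UE on lesion anatomy (it is an independent draw by
default). Green tests therefore certify the statistical machinery under a
correctly specified linear model with geometric masks — not robustness to
the messier anatomy of real lesion data.

### Parameter-recovery conditions

The recovery simulations use n = 200 cohorts with effects configured, after
measuring the synthetic load scale (sd of the PMD load is roughly 100
weighted voxels under the default geometry), so that all three standardized
effects are strong and floor/ceiling clamping is negligible:
$\beta_0 = 15$, $\beta_{fm} = 0.7$, $\beta_{ll} = -0.02$,
$\beta_{age} = -5$, $\sigma = 3$. Under these conditions stepwise selection
should recover exactly the three generative predictors in at least 95% of
100 replications, and bootstrap/OLS 95% intervals should cover the true
coefficients at close to nominal rates. Clamping matters here: stronger
lesion effects push severely lesioned subjects below the FM-UE floor, which
truncates residuals and biases the lesion coefficient — visible degraded
coverage, not a code defect, and the reason the recovery conditions keep
clamping rare while the n = 27 demo defaults tolerate mild ceiling effects
as real FM-UE data show.

## A worked example

```{r example, eval = FALSE}
out <- tempfile("demo-")
cfg <- run_config(out, seed = 27, n_subjects = 27,
                  B_dominance = 1000, B_coef = 1000)
res <- run_full(cfg)

glance(res$stepwise)          # steps, R^2, adjusted R^2, SEE
res$stepwise$steps            # the stepwise summary table
glance(res$dominance)         # general weights sum to full-model R^2
reproducibility_range(res$reproducibility)
autoplot(res$dominance)       # conditional dominance curves
plot_age_grouping(res$cohort) # outcome vs load, by age group
```

Numerical choices collected in one place: affine grid agreement to 1e-4
absolute per element (registration is out of scope; the tolerance absorbs
float serialization); binarization maps any strictly positive voxel to 1
with a logged warning; the axial direction is the third array axis after
closest-to-RAS reorientation, which makes the slice quantities $n(x)$,
$m(x)$ well defined; voxel indices are 1-based (R convention); $\Delta R^2$
clipping at $-10^{-10}$; rank-deficient subsets use SVD pseudo-solutions
and are flagged, never silently dropped; degenerate bootstrap resamples are
redrawn at most 100 times.

## Limitations

Registration, lesion segmentation, and diffusion processing are out of
scope — inputs must already share a voxel grid. The union-profile choice for
the whole-CST load and the per-pair reproducibility-range convention are
documented decisions among defensible alternatives. Stepwise selection
inherits all the usual caveats of data-driven model selection at small n;
the dominance bootstrap quantifies within-sample stability only.
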
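---
title: "Mixed-model transcriptome scans for PCB exposure and leukocyte interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed-model transcriptome scans for PCB exposure and leukocyte interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcbscan)
```

## The scientific problem

Serum polychlorinated biphenyls (PCBs) are persistent, lipophilic pollutants
with suspected sex-specific and immune-mediated health effects, including an
association with B-cell lymphoma risk. In a prospective cohort with archived
blood transcriptomes, the natural question is which transcripts change with
the serum level of each individual congener, whether those changes differ
between women and men, and whether they depend on the composition of the
white-blood-cell (WBC) pool — either because exposure shifts the pool or
because different cell types respond differently.

Three nuisance structures make a naive per-transcript regression unreliable:
technical batch variation tied to the microarray scan date, confounding by
demographics (cohort of origin, sex, age, BMI, smoking, future cancer
status), and the cellular heterogeneity of whole blood. This package carries
the full analysis chain that addresses them: microarray-style preprocessing,
reference-based WBC deconvolution from DNA methylation, collinearity
screening of the covariates, per-transcript linear mixed models with a
scan-date random intercept, and the downstream stratified summaries — plus a
synthetic-cohort generator with planted ground truth so that every stage can
be verified quantitatively.

## The model

For subject $i$ and one transcript, expression $Y_i$ is modelled as

$$Y_i = \alpha + \beta_1 \mathrm{PCB}_i + \beta_2 \mathrm{WBC}_i +
        \beta_3\, \mathrm{PCB}_i \times \mathrm{WBC}_i +
        \beta_4 \mathrm{FE}_i + u_{A(i)} + \varepsilon_i,$$

where $\mathrm{PCB}_i$ is the (transformed) serum level of one congener,
$\mathrm{WBC}_i$ a leukocyte fraction, $\mathrm{FE}_i$ the fixed-effect
confounders (cohort, sex, type of future cancer, age, BMI, smoking, and the
remaining cell fractions), $u_{A(i)} \sim N(0, \sigma^2_u)$ a random
intercept shared by all subjects scanned in the same batch $A(i)$, and
$\varepsilon_i \sim N(0, \sigma^2_e)$ residual noise. The main-effect scan
([`lmm_scan()`]) omits the product term; the interaction scan
([`interaction_scan()`]) tests exactly the product, always keeping both main
effects in the model, so its test has one degree of freedom.

### Fitting

`fit_lmm()` maximizes the marginal ML likelihood by profiling. Writing
$\lambda = \sigma^2_u/\sigma^2_e$, the covariance is
$\sigma^2_e (I + \lambda Z Z^\top)$ for the batch indicator matrix $Z$; for
fixed $\lambda$, the GLS coefficients and $\hat\sigma^2_e$ are closed form,
and because $Z$ encodes a single grouping factor every quantity reduces to
per-batch sums ($V_j^{-1} = I - \tfrac{\lambda}{1+\lambda n_j}J$,
$\log|V| = \sum_j \log(1+\lambda n_j)$). The one-dimensional profile is
maximized over $\log\lambda \in [\log 10^{-8}, \log 10^{3}]$ with tolerance
$10^{-8}$, and the $\lambda = 0$ boundary (no batch variance) is always
admitted; a single batch forces $\lambda = 0$, where the fit equals ordinary
least squares exactly. ML rather than REML is used throughout because the
scans compare models with different fixed effects. The per-scan design work
is shared across transcripts, which is what makes transcriptome-wide scans
of thousands of transcripts take seconds rather than hours.

### Inference

Evidence for the variable of interest is the likelihood-ratio statistic
$2(\ell_{\text{full}} - \ell_{\text{reduced}})$, floored at zero.
`lrt_nested()` refers it to a chi-square with the difference in fixed-effect
count as degrees of freedom. Inside the scans the same statistic is mapped
to an F reference, $F = (e^{\mathrm{LRT}/n}-1)(n-p)/q$ on $(q, n-p)$ degrees
of freedom: in the $\lambda = 0$ limit this mapping is the exact F test, and
asymptotically it coincides with the chi-square reference, while avoiding
the chi-square's slight far-tail anticonservativeness at realistic scan
sample sizes — the far tail is precisely what survives multiplicity
correction, so calibration there matters most. A coefficient-level Wald test
is available behind `scan_spec(test = "wald")` for sensitivity analysis;
likelihood-ratio is the default because single-coefficient evidence and
model-comparison evidence coincide asymptotically and the LRT respects the
profile geometry at boundary-ish variance ratios.

Multiplicity is controlled per scan with the Benjamini–Hochberg step-up at
FDR 0.05 (`bh_fdr()`; the relaxed 0.2 preset is one argument away), matching
the convention of reporting significant-transcript counts per (stratum ×
congener × cell type) scan. A global-FDR alternative is a matter of calling
`bh_fdr()` on the pooled p-values. Transcripts with essentially zero
variance (below $10^{-12}$) are flagged and excluded from the BH
denominator.

### Exposure scale

Serum PCB concentrations are strictly positive and right-skewed, and the
source data do not fix a transformation; the default is log then z-score
within the analyzed stratum (`exposure_transform = "log_zscore"`), which
makes scan p-values invariant to the units of the raw exposure and makes
effect sizes comparable across congeners. All four combinations are
available.

## Covariate hygiene

`compute_vif()` implements the textbook variance inflation factor,
$\mathrm{VIF}_j = 1/(1-R^2_j)$, with exact collinearity reported as `Inf`
rather than an error, and `screen_variables()` removes worst-first until all
retained covariates clear the threshold (default 4, the usual rule of
thumb). Two structural decisions are encoded as defaults because the six
serum congeners are strongly mutually correlated and the six cell fractions
sum to one: each scan carries a single congener as the variable of interest,
and granulocytes — the dominant fraction — are dropped from the WBC
covariate set (`cohort_design_for_vif()` documents the same choice for the
screening design). When an interaction scan targets granulocytes themselves,
the design builder re-opens the simplex by dropping a different fraction so
the model stays full rank.

## White-blood-cell deconvolution

`estimate_cell_fractions()` performs reference-based cell-mixture
deconvolution: each subject's methylation beta-profile is projected onto
purified-leukocyte reference signatures by nonnegative least squares
(Lawson–Hanson), with the sum-to-one constraint imposed when the
unconstrained-sum solution exceeds one and the returned vector renormalized
onto the simplex. Whether the original analyses constrained the sum to be
exactly one or at most one is not recoverable; both behaviours are exposed
(`constraint = "inequality"` / `"equality"`) and end on the simplex either
way. Selecting discriminating CpGs and building the reference from purified
samples are out of scope — the reference is taken as given.

## Preprocessing

The microarray-style preprocessing follows the standard sequence: probe
measurements with less than 75% of the maximum possible pixel count are set
missing ("at least" semantics, so a fraction of exactly 0.75 is retained);
missing values are imputed with k-nearest-neighbour means (k = 15,
Euclidean distance over co-observed positions on mean-centred profiles,
rescaled by $\sqrt{p/p_{\mathrm{obs}}}$ so distances are comparable across
overlap sizes); and arrays are quantile-normalized (every column receives
the mean sorted profile by rank, ties averaged). Whether imputation
originally preceded normalization is unstated; the default order is filter
→ impute → normalize, and the other order is one flag away
(`preprocess_pipeline(impute_first = FALSE)`). A within-array intensity
correction is a two-colour-chemistry step that single-channel synthetic data
does not need and the pipeline does not include.

## The synthetic cohort: what it emulates, and what it does not

`generate_cohort()` draws the structure the analysis assumes: 512 subjects
(217 future lymphoma cases, 295 controls) by default; two cohort labels;
six log-normal serum congeners coupled by a Gaussian copula with pairwise
correlation 0.6 (serum congeners are strongly correlated); Dirichlet WBC
fractions with concentrations centred on typical whole-blood proportions
(granulocytes ≈ 60%); 20 scan-date batches with at least two subjects each;
and truncated-normal follow-up times (mean 5.96 y, sd 2.85 y, bounds 2–17 y)
for future cases. Females receive a +0.5 SD shift of the log-location for
congeners 118, 156, 170 and 180, reproducing the qualitative sex-difference
pattern for exactly those congeners. The shift size was set by an a-priori
power analysis: with roughly 256 subjects per sex, 0.5 SD gives per-congener
two-sample-t power above 0.999, so the pattern is a property of the
generator rather than a marginal event, whereas a 0.3 SD shift would leave
each congener at ≈ 0.92 power and the joint pattern near a coin flip across
replicate cohorts.

`generate_expression()` builds the linear predictor of the model above on
the standardized-log-exposure scale (the same scale the default scan fits
on), applies an optional per-transcript sex mask so female-only or male-only
responses can be planted, and adds the batch random intercept
($\sigma^2_u = 0.2\,\sigma^2_e$ by default — batch noise is real but smaller
than residual noise; the source quantifies neither) and iid Gaussian noise.
`simulation_truth()` holds the planted coefficients and
`interaction_effect_for_power()` converts a target power into the
interaction coefficient appropriate for a given realized cohort, via the
noncentrality identity $\mathrm{ncp} = \beta^2\,\mathrm{SSR}(x)/\sigma^2_e$
with the product term residualized on all other covariates. When the target
is a BH-controlled scan over $m$ transcripts with true-effect fraction
$\pi_1$, "80% per-test power" is operationalized at the self-consistent
per-test level $\alpha \approx \mathrm{FDR}\cdot\pi_1\cdot 0.8$ — the
expected BH step-up threshold — because per-test power at the nominal 0.05
is unattainable by any method once the step-up threshold is two orders of
magnitude smaller.

What the generator does *not* emulate: real exposure magnitudes and units,
array noise spectra (heteroskedastic, probe-dependent), probe-level
annotation structure, correlated transcripts (co-expression), or
cohort-specific batch nesting. Passing tests therefore demonstrate that the
statistical machinery is correct and calibrated under the assumed model,
not that results from any particular real cohort are reproduced;
cohort-specific transcript counts depend on restricted subject-level data
and are not targets.

## Power

`power_linear_model()` is the noncentral-F power of the fixed-effects test
in Cohen's $f^2$ parameterization
($\mathrm{ncp} = f^2 (u+v+1)$, power $= P(F' > F_{1-\alpha;u,v})$), exact at
$f^2 = 0$ where it returns $\alpha$; `f2_for_power()` inverts it.

## Numerical choices and degenerate inputs

* $\lambda$ search: `optimize()` on $\log\lambda$, bounds $[10^{-8}, 10^3]$,
  tolerance $10^{-8}$; the returned solution is compared against the
  $\lambda = 0$ boundary and the better one kept.
* A singular full design is an error at scan setup; a transcript whose fit
  fails numerically is flagged `converged = FALSE` with missing p.
* Quantile-normalization ties are broken by averaging the reference values
  at tied positions; `rank(ties = "average")` with interpolation between
  the bracketing reference values.
* Deconvolution's sum constraint uses a weighted augmentation row followed
  by an exact KKT refit on the active set, so equality solutions carry no
  penalty error.
* VIF treats $R^2 \ge 1 - 10^{-12}$ as exact collinearity (`Inf`); screening
  ties break to the first maximum, and the removal order is logged.
* Batch correction (`batch_correct()`) subtracts the per-batch BLUPs,
  $\hat u_j = \lambda r_j/(1+\lambda n_j)$ for batch residual sums $r_j$,
  from each transcript before time-to-diagnosis correlations; the
  correlation is Pearson by default with Spearman behind a flag.
* The lymphoma-profile comparison uses per-gene Welch t-tests on log2
  intensities with $|\mathrm{FC}| \ge 1.5$ applied as
  $|\log_2 \mathrm{FC}| \ge \log_2 1.5$; empirical-Bayes variance
  moderation is a deliberate non-goal, so small-sample variance estimates
  are noisier than a moderated analysis would give.

## Problem sizes used in verification

The shipped verification suite exercises the pipeline at desk scale chosen
to make every property measurable with comfortable margins: null
calibration on cohorts of 300 subjects × 2000 transcripts × 10 batches over
20 replicate generations; planted-effect recovery at 500 subjects with 5%
of 2000 transcripts carrying the 80%-power interaction effect; variance
recovery at 40 batches × 25 subjects; deconvolution at 200 CpGs × 100
subjects with noise sd 0.02; and exact-oracle comparisons (dense-matrix
likelihood grids, active-set enumeration, combinatorial enumeration,
quadrature) on fixtures small enough for brute force.

## A worked example

```{r example, eval = FALSE}
library(pcbscan)

coh <- generate_cohort(n = 512, n_cases = 217, seed = 1)
exposure_sex_ttest(coh)          # which congeners differ by sex?

truth <- plant_interaction(simulation_truth(1000), 1:25, "156", "B",
                           effect = 4, sex = "F")
expr <- generate_expression(coh, truth, seed = 2)

res_F <- interaction_scan(expr[, coh$sex == "F"],
                          droplevels(coh[coh$sex == "F", ]), "156", "B")
res_M <- interaction_scan(expr[, coh$sex == "M"],
                          droplevels(coh[coh$sex == "M", ]), "156", "B")
summary(res_F)$n_significant     # recovers planted female-only effects
summary(res_M)$n_significant     # ~0: nothing planted in males

tab <- stratified_scan_counts(expr, coh, strata_plan = "sex_case",
                              pcbs = c("156", "170"), wbcs = c("B", "Mono"))
tab
```

## Known limitations

Single random intercept only (no crossed or nested random effects, no
kinship); no REML; no moderated-variance differential expression; gene-set
and known-gene lists are user-supplied files, as pathway databases and
web services are outside the package; and the synthetic generator targets
statistical structure, not biological realism, as discussed above.
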
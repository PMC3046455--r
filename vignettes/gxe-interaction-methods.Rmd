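---
title: "Testing gene-environment interaction in pooled case-control studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing gene-environment interaction in pooled case-control studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gxeminp)
```

## The scientific problem

Common breast cancer susceptibility alleles confer small per-allele relative
risks (odds ratios around 1.05-1.25). Risk prediction models typically
combine these genetic effects with reproductive and anthropometric risk
factors — age at menarche, parity, age at first birth, body mass index —
under the assumption that the joint effect is multiplicative. `gxeminp`
implements the machinery for testing that assumption in pooled multi-study
case-control data: per-allele main-effect models, risk-factor trend models,
category-stratified per-allele odds ratios, a one-degree-of-freedom
product-term interaction scan across a grid of SNP-by-factor pairs, and a
single-step min-p family-wise multiple-testing adjustment built by
parametric bootstrap (or within-study permutation).

Because individual-level consortium data are not publicly distributable,
the package pairs the analysis machinery with a synthetic cohort generator
that emulates the statistical structure such data have — many case-control
studies of very different sizes, Hardy-Weinberg genotypes at configurable
risk-allele frequencies, correlated reproductive variables, per-field
missingness, and configurable main and interaction effects. Every claim the
test suite makes about the analysis code is a claim verified on that
generator.

## Models

**Per-allele (multiplicative) genotype coding.** Genotypes enter all models
as risk-allele dosage $d \in \{0, 1, 2\}$, so the per-allele odds ratio
$e^{\beta_g}$ multiplies once per allele copy. Overall SNP effects are
estimated from logistic regression of case status on dosage with study as a
categorical covariate; subset analyses additionally adjust for age
(categorical bins $\le 34, 35\text{-}39, \ldots, \ge 75$ *and* continuous —
the continuous term absorbs residual confounding inside the extreme bins)
and for the risk factor defining the subset.

**Risk-factor trends.** Each factor has a continuous coding on its natural
scale — years for age at menarche and age at first birth, live births for
parity count, kg/m$^2$ for BMI, 0/1 for ever having had a live birth — and
an ordered category system for stratified reporting. Trend odds ratios are
estimated with study and age adjustment; age at first birth is reported per
5-year increment (the fitted per-year OR to the fifth power).

**Stratified per-allele ORs from one joint model.** For a SNP and a
factor's category system, a single study-adjusted fit contains the category
main-effect dummies, a common dosage slope and per-category dosage
deviations. Per-category per-allele log-ORs are contrasts of these
coefficients, and the likelihood-ratio test of the deviation terms against
the common-slope model is a homogeneity test across categories. Categories
containing a single outcome class are flagged and omitted; the rest of the
table is still produced.

**The interaction model.** For each (SNP, factor) pair the full model is

$$\operatorname{logit} P(\text{case}) = \alpha_{\text{study}} +
\beta_g d + \beta_e x + \beta_{ge}\, d x,$$

with $x$ the factor's continuous coding, fitted on the pair's complete-case
subset (parous women only for parity count and age at first birth; the
relevant age stratum for BMI, with 55 years as the boundary assigned to the
older stratum, a surrogate for menopausal status). The test is the 1-df
likelihood-ratio comparison against the model without the product term.
$e^{\beta_{ge}}$ is the interaction OR: the multiplicative change in the
per-allele OR per unit of the factor. Because both main effects are in the
model, $\beta_{ge}$ is invariant to shifting the factor by a constant. The
default grid is 12 SNPs crossed with six factors (menarche, ever-birth,
parity count, age at first birth, BMI under 55, BMI 55 and over): 72 tests.

**Min-p adjustment.** Unadjusted p-values in a 72-test family need a
family-wise correction that respects the dependence between tests sharing
subjects and covariates. For each test, the main-effects-only model
(everything but the product term) is fitted and each subject's probability
of being a case recorded. Each of $B$ replicates draws one uniform per
subject, assigns a dummy case status per test by comparing that uniform
with the test's null probability (so replicate outcomes are coherent across
tests that share subjects), refits full and null models per test against
the real covariates, and records the minimum LRT p-value over the grid. The
adjusted p-value of a test is the proportion of replicate minima strictly
below its unadjusted p-value. The permutation variant replaces the redraw
with a within-study permutation of the observed labels. With independent
tests, both converge to the Šidák form $1 - (1-p)^m$; the package exposes
that and the Bonferroni per-test threshold $\alpha/m$ (0.000694 for
$m = 72$, $\alpha = 0.05$) as closed-form baselines.

Two counting rules are provided: the strict rule `#(minp < p)/B` (the
default, faithful to the single-step procedure as usually described, but
able to return exactly 0) and the `add_one` rule `(count+1)/(B+1)`, which
cannot. `add_one` is never smaller than strict.

## The logistic core

All fitting goes through one iteratively reweighted least squares routine
(compiled, Armadillo): convergence when every score component is below
`1e-8`, at most 100 iterations, step-halving whenever a Newton step would
decrease the log-likelihood beyond its rounding noise. Continuous columns
are centred internally for conditioning; results are reported on the
original scale. Two failure modes are first-class errors rather than silent
misbehaviour: (quasi-)complete separation, detected as a coefficient
diverging past 15 on the log-odds scale with a non-vanishing score, and
rank deficiency, reported with the dependent column names. During
bootstrap replication, a replicate fit that fails is dropped from that
replicate's minimum and counted; if more than 1% of all replicate fits
fail, the adjustment aborts — that typically signals studies too small to
support the study-dummy parameterisation rather than bad luck.

The suite checks the fitter against `glm()` (coefficients, covariance,
log-likelihood) and against the exact cross-product-ratio closed form on
2x2 designs; `glm` is never used inside the package itself.

## The synthetic cohort generator

The generator mirrors the analysis model used generatively, plus structure
the analysis must cope with:

* **Ascertainment.** Per study, records are drawn from a population model,
  disease status is sampled from the logistic probability, and cases and
  controls are accumulated by rejection until the target counts are met.
  Study intercepts are calibrated by root-finding so the expected
  prevalence hits a target (default 10%, admissible band 5-20%) — keeping
  rejection efficient and intercepts interpretable.
* **Genetics.** Independent Hardy-Weinberg dosages per SNP
  (Binomial(2, q)). No linkage disequilibrium is simulated: each SNP is
  analysed marginally, so LD would not exercise any additional code path.
* **Reproductive structure.** Age at first birth exists only for parous
  women and is strictly below current age; parity count is drawn
  conditional on age at first birth (earlier first births give larger
  families), inducing realistic correlation structurally rather than
  through a copula.
* **Risk-factor distributions.** The defaults are conventional for
  European-ancestry study populations — menarche discretised around 13
  years, first births centred at 25, 85% parous, log-normal BMI around
  25.5, age truncated-normal around 57 — and are configuration fields, not
  claims about any particular consortium. The packaged
  `bcac_sim_config()` uses 21 studies with realistic case/control counts
  (about 26,000 cases and 32,000 controls), the default catalog's
  frequencies and per-allele ORs, protective trends for later menarche
  (OR 0.96/year), parity (0.84), parity count (0.89/birth), an adverse
  trend for later first birth (1.07 per 5 years), an inverse BMI trend
  confined to women under 55, and one built-in interaction: OR 1.05 per
  risk allele of the LSP1-region SNP per live birth.
* **Missingness and subtypes.** Per-field missingness rates make
  per-analysis sample sizes vary across the grid, as in pooled data;
  ER/PR status is assigned to cases only, optionally genotype-dependent.
* **Determinism.** One master seed spawns per-study, per-field, and
  per-replicate substreams (a rolling-hash seed derivation), so adding a
  study never perturbs other studies' draws, results are independent of
  chunking, and a configuration plus seed reproduces output files
  byte-identically.

What the generator deliberately does not emulate: between-study
heterogeneity in questionnaire semantics, population stratification,
genotyping error, LD, and selection mechanisms that differ between cases
and controls. Passing tests therefore demonstrate that the statistical
machinery is correct under the stated generative law — not that any real
consortium dataset satisfies that law.

## Numerical and design choices

* Interaction models adjust for study only (age adjustment is available as
  a sensitivity option); stratified-OR tables likewise default to
  study-only adjustment. Main-effect trend models always adjust for age.
* Reference categories are deterministic: first study label in sort order,
  lowest factor category.
* In the generative logit, continuous covariates are centred at typical
  values (menarche 13, first birth 25, BMI 25.5, age 55); this only moves
  the calibrated intercept. Interaction products use the factor's natural
  scale.
* The strict counting rule is the default for fidelity to the single-step
  min-p procedure; `add_one` exists because strict can return exactly 0.
* Whether the replicate minimum should run over the full 72-test family or
  sub-families is a genuine reading choice; the joint minimum is
  implemented, and the `grid` argument of `gxe_scan()` permits sub-family
  runs.
* Power simulation requires an explicit exposure distribution in the
  design. Published minimum-detectable interaction ORs from analytic
  calculators depend on exposure distributions that are rarely reported,
  so qualitative orderings (rarer allele implies larger minimum detectable
  OR) are the reproducible content, and that is what the suite asserts.

## What the test suite runs

Problem sizes were chosen so the default suite completes in minutes while
keeping each check statistically meaningful:

* null calibration: 2,000 simulated null cohorts (3 studies of
  2,000/2,000), Kolmogorov-Smirnov uniformity of the interaction LRT
  p-values at the 1% level;
* family-wise error: 200 null repetitions of a 3-SNP x 2-factor grid at
  B = 500, rejection fraction inside the exact binomial 95% band around
  0.05;
* recovery: 100 cohorts of 25,000/25,000 with interaction OR 1.05 per
  allele per birth, 95% CI coverage of at least 90/100;
* oracle equivalence: cross-product ratio to 1e-8; Šidák agreement within
  0.01 at B = 10,000 on six near-independent tests; bootstrap-permutation
  agreement within 0.02 at B = 2,000;
* power: size equals level within 3 Monte-Carlo SEs; monotonicity in
  effect size and sample size; allele-frequency ordering of the minimum
  detectable OR.

`scripts/acceptance.R` recomputes the package's headline quantities from a
single seed: the 72-test grid, the 0.000694 per-test threshold, the Šidák
value 0.134 for p = 0.002 over 72 tests, consortium-scale recovery of the
1.05 interaction OR and of the main-effect trends (4% per menarche year,
16% for parity, 11% per birth, 7% per 5 years of first-birth age, FGFR2
per-allele OR 1.22), a full 72-test scan with min-p adjustment on a
reduced-scale 21-study cohort, and the null size of the Monte-Carlo power
estimator.

## A worked example

```{r example, eval = FALSE}
cfg <- bcac_sim_config(scale = 0.15)      # 21 studies, reduced size
cohort <- simulate_cohort(cfg, seed = 1)
scan <- gxe_scan(cohort, catalog = cfg$catalog)
summary(scan)
adjusted <- adjust_minp(scan, cohort, B = 500, seed = 2)
print(adjusted)
top <- scan[which.min(scan$p), ]
plot(stratified_per_allele_ors(cohort, top$snp, top$factor, cfg$catalog))
```

## Known limitations

* The bootstrap refits two models per test per replicate; with many small
  studies the study-dummy parameterisation can make replicate fits fragile
  (the 1% failure guard exists for this). Absorbing study strata by
  conditional likelihood would scale better and is not implemented.
* Only the single-step min-p adjustment is provided; step-down refinements
  and FDR procedures are out of scope.
* Exact logistic regression, penalised fits and robust/clustered variances
  are not implemented; separation is an error by design.
* The generator's case-control sampling is exact retrospective sampling
  from a single logistic law per study; it cannot represent differential
  selection of controls.
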
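---
title: "Models and methods: BMI effects on fasting, postprandial and meal-response metabolites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis problem

Metabolite abundance is a dynamic trait. A person's nuclear-magnetic-resonance
metabolome looks different after an overnight fast than it does 150 minutes
after a standardized liquid mixed meal, and the *change* between those two
states — the meal response — is a phenotype in its own right. This package
estimates how body mass index (BMI, kg/m²) relates to metabolite traits in
three dietary states:

* **fasting** abundance,
* **postprandial** abundance (after a meal challenge),
* **response**, the deviation of the postprandial value from what the fasting
  value predicts.

Two inferential frameworks are run side by side for every trait:

1. an **observational** weighted multivariable regression,
   `metabolite ~ visit_date + subpopulation + age + sex + bmi`, and
2. a **one-sample Mendelian randomization (MR)** analysis by weighted
   two-stage least squares (2SLS), instrumenting BMI with a weighted
   polygenic score (PGS) built from external GWAS variant weights.

Concordant estimates across the two frameworks support a causal reading of
the observational associations; the MR machinery carries the standard
diagnostics (weak-instrument *F*, Durbin–Wu–Hausman endogeneity test,
Breusch–Pagan homoskedasticity test, sequential η²).

The cohort design the pipeline assumes has two subpopulations: one sampled at
random and one *oversampled for BMI above 27*, with sampling weights that make
the oversampled stratum's BMI distribution emulate the random one. Visit
dates are structured by subpopulation, which makes sampling date a genuine
BMI covariate; it is adjusted for in every model.

# The response phenotype

For each trait, postprandial abundance $y$ is regressed on fasting abundance
$x$ by **Deming regression**, the errors-in-both-variables estimator. With
centered sums of squares $s_{xx}, s_{yy}, s_{xy}$ and error-variance ratio
$\lambda = \sigma^2_{\varepsilon_y} / \sigma^2_{\varepsilon_x}$,

$$\hat\beta \;=\; \frac{s_{yy} - \lambda s_{xx} +
  \sqrt{(s_{yy} - \lambda s_{xx})^2 + 4\lambda s_{xy}^2}}{2 s_{xy}},
  \qquad \hat\alpha = \bar y - \hat\beta \bar x .$$

The response trait is the vector of **vertical residuals**
$r_i = y_i - (\hat\alpha + \hat\beta x_i)$: positive values mean a higher
postprandial abundance than the fasting level predicts. Residuals are kept on
the postprandial scale (rather than as orthogonal projections) precisely so
that this sign interpretation holds; whether a reference implementation would
return vertical or orthogonal residuals is unknowable from the available
description, so this is a documented design choice, not a fact. A simple
$\Delta = y - x$ response is available as an alternative
(`method = "delta"`); on the synthetic data the two correlate strongly
(per-trait Pearson r > 0.6 is asserted by the tests; real NMR data show mean
r ≈ 0.94).

Three numerical facts about this estimator that the test suite pins down:

* the closed form matches an independent numeric minimizer of the weighted
  orthogonal loss $\sum_i (y_i - a - b x_i)^2 / (\lambda + b^2)$ to $10^{-6}$;
* as $\lambda \to \infty$ the slope converges to the OLS slope of $y$ on $x$;
* Deming regression is **not** scale-equivariant at fixed $\lambda$: rescaling
  $y \mapsto cy$ rescales the $y$-error variance by $c^2$, so the slope scales
  by $c$ only when $\lambda \mapsto c^2\lambda$ accompanies it. (A naive
  "multiply $y$ by $c$, keep $\lambda$" equivariance claim is false, and the
  property test asserts the correct version.)

$\lambda$ defaults to 1 — equal error variances in the two states, which is
also what the synthetic generator produces — and is exposed as a parameter.
`sxy = 0` carries no orientation information and is treated as a degenerate
fit; such traits are skipped and logged. Fits use complete pairs only;
residuals are computed wherever both values exist.

# Quality control

The cleaning chain runs in a fixed order, mirroring how raw assay matrices
are actually repaired:

1. **zeros to missing** — exact zeros are below-detection codes, not
   abundances;
2. **univariate 10-IQR filter** — per trait and state, values more than
   $k = 10$ interquartile ranges from the median become missing (zero-IQR
   traits are left alone with a warning);
3. **bivariate filter** — a preliminary Deming fit ($\lambda = 1$) of
   postprandial on fasting per trait; pairs whose residual is more than
   $k = 10$ residual-IQRs from the residual median become missing *in both
   states*. The multiplier matches the univariate rule for symmetry; traits
   with fewer than 10 complete pairs are skipped;
4. **feature-then-sample missingness filter** at 20%/20% defaults (the
   conventional metabolomics-QC thresholds; both exposed as parameters).

The QC report reconciles exactly: every cell the rules touch is counted, and
the tests assert the missingness deltas match the per-rule totals. On clean
Gaussian data the false-flag rate of each rule is below 0.1%; injected gross
outliers (placed ≥ 12 IQR out by the generator) are recalled completely.

# Transformation and multiplicity

Each trait (all three states) is **rank-based inverse-normal transformed**
before modeling: $z_i = \Phi^{-1}\!\big((r_i - 3/8)/(n + 1/4)\big)$ with ranks
$r_i$ and the Blom offset $3/8$ (offsets 0 and 0.5 available). Ties are
randomly ranked under a dedicated, logged seed, so a pipeline run is exactly
replayable while the output multiset is seed-invariant. Effects are therefore
reported in **SD units per BMI unit**. A Shapiro–Wilk screen (flag at
W < 0.95, subsampling to 5000 observations where needed) documents why the
transformation is applied: raw NMR traits are heavily non-normal, while model
residuals on transformed outcomes reach W > 0.99.

Because the 3 × n_traits outcome set is highly correlated, Bonferroni
correction uses the **effective number of independent traits**: hierarchical
clustering (average linkage) on the distance $1 - |\rho|$ (Spearman), tree cut
at height 0.5, one representative per cluster (the medoid under the same
distance, lexicographic tie-break — the reference clustering tool's exact
selection rule is not documented, so the medoid is a package decision). The
threshold is $\alpha / n_{\mathrm{eff}}$; the analytic anchors
$0.05/43 = 1.163\times10^{-3}$ and $0.05/54 = 9.26\times10^{-4}$ are pinned in
the tests.

# Polygenic score construction

GWAS weight rows are harmonized against cohort variants: exact allele match
is kept; a match after swapping effect/other alleles is kept with the effect
size negated (re-orienting the effect to the cohort's counted allele —
algebraically identical to the $d \mapsto 2-d$ dosage map up to an additive
constant); anything else is dropped, as is any variant whose folded minor
allele frequency differs from the cohort's by more than 0.1. Palindromic A/T
and C/G variants are retained and rely on that frequency guard; no strand
flipping is attempted. Effects are then aligned positive (so every effect
allele is BMI-increasing; rankings are unchanged because alignment adds a
constant $2\sum|w|$ over flipped variants), and the score is
$\mathrm{PGS}_i = \sum_j w_j d_{ij}$. Missing dosages contribute the
Hardy–Weinberg expectation $2 \times$ effect-allele frequency, with the
imputed-cell count logged.

# The weighted models

The observational model is a Gaussian identity-link GLM — i.e. weighted least
squares — with BMI entered **last**, so the sequential (type I) decomposition
attributes to BMI only variance beyond the covariables:
$\eta^2_{\mathrm{BMI}} = SS_{\mathrm{seq}}(\mathrm{BMI})/SS_{\mathrm{tot}}$.
Weighted runs use weighted sums of squares throughout (the alternative —
unweighted SS inside a weighted fit — mixes estimands).

2SLS: stage 1 regresses BMI on PGS + covariables, stage 2 regresses the
outcome on the fitted BMI + covariables, both stages carrying the same
sampling weights. Standard errors use the proper 2SLS variance — residuals
formed with the *observed* exposure — not the naive stage-2 OLS variance. The
homoskedastic variance is the default (matching standard IV-regression
behavior); an HC0 sandwich is available behind `robust = TRUE`. The
weak-instrument partial *F* (flag below 10), the Durbin–Wu–Hausman
augmented-regression test ($\chi^2_1$ on the squared t of the stage-1
residual term), and Breusch–Pagan accompany every fit.

**A note on Breusch–Pagan under sampling weights.** The test regresses
squared *weighted* residuals on the design. When the data are homoskedastic
but the weights vary, $\mathrm{Var}(\sqrt{w_i}e_i) = w_i\sigma^2$ is
heteroskedastic by construction and predictable from the design (weights are
a function of BMI), so the weighted-run BP correctly rejects its own null.
Size calibration of the test is therefore asserted under its actual null —
fits with constant weights — where the empirical size sits inside [3%, 7%].

Weighted-lm standard errors treat the weights as precision weights, exactly
as a plain `glm(..., weights = )` call would; under sampling weights this is
an approximation whose direction depends on the weight–leverage correlation.
In the synthetic world the weights are nearly flat (see below), the
approximation is mild, and 95% CI coverage over 200 replicate cohorts stays
inside [90%, 99%] for both frameworks and both tested states.

# The synthetic cohort: a stated world

No public individual-level data exist for this design, so the package ships a
generator whose statistical structure is the analysis' assumed world, with
defaults matching the published design: 1406 + 4111 individuals, threshold
27, 656 variants (≈ 646 surviving harmonization), PGS R² 0.045 (the published
wNEO estimate is 0.0431), date structure R² 0.20 (published: 20.3%), 229
traits in 14 classes.

**BMI.** The base population is $\mathcal N(26.2, 4.4^2)$ (matching the
random stratum's published mean and 95% interval width) plus PGS, date, sex
and age terms. The oversampled stratum draws its noise from the truncated
conditional distribution via the inverse CDF — equivalent in distribution to
rejection-sampling the noise until BMI exceeds the threshold, but
deterministic and loop-free. Two coefficients are calibrated by a fixed-point
loop (noise stream held fixed) so the *realized pooled* univariable R² of PGS
and date hit their configured targets; the calibration is part of the
generator's contract ("scaled so the PGS explains the configured fraction"),
not a tuning knob.

**Metabolites.** Each trait has a latent biological component
$x^* = \beta_f B + \gamma d + \sqrt{w}\,f_c + u$ measured twice with
independent errors: fasting $= \mu + x^* + m_1$ and postprandial
$= 1.05\mu + s\,x^* + (\beta_p + \beta_r) B + m_2$. This latent form — rather
than regressing postprandial on *observed* fasting — is exactly the
errors-in-both-variables structure that justifies Deming regression, and it
is the only form under which "betas in SD units" is a coherent contract: the
variances are solved in closed form so that both states have unit variance,
the between-state covariance is 0.5, the λ = 1 Deming slope estimand is
exactly 1, and the Deming residual has unit variance. Consequently a
configured $\beta_r$ *is* the SD-unit effect the downstream response model
estimates, with no hidden attenuation. Each trait carries one effect type
(fasting, postprandial, response, or none, assigned cyclically) scaled by a
per-trait multiplier from $\{-1, -\tfrac12, \tfrac12, 1\}$; a fasting-effect
trait also shows an attenuated postprandial association ($s\beta_f$) through
the shared latent component, as real data would. The date loading
$\gamma = 0.1$ SD gives visit date a BMI-independent path into the traits,
so omitting the date covariate genuinely shifts the BMI coefficient — the
confounding the models must adjust away.

**Weights.** Density-ratio weights over 20 equal-count BMI bins of the
random stratum, renormalized to mean 1 in the oversampled stratum. Because
the oversampled stratum is the same base population conditioned on BMI > 27,
the density ratio is constant over the shared support, so the derived
weights are nearly flat — the weighted analysis is honest but undramatic
here. Real designs with genuinely different base populations would produce
more variable weights; the identical-distributions property (weights within
0.1 of 1) needs the per-bin counts to dominate binning noise (the max
deviation shrinks like $\sqrt{2\cdot 20/n}$), and is asserted at n = 10⁵ per
stratum.

**What a green test does not establish.** The generator emulates the
*statistical* skeleton: two strata, truncation, date confounding, a
PGS→BMI→trait causal chain, correlated trait blocks, fasting–postprandial
correlation 0.5, missingness and gross outliers. It does not emulate NMR
measurement chemistry, skewed concentration distributions (traits are
Gaussian before corruption; the RINT step is therefore exercised for its
contract, not its necessity), inter-trait ratio structure, imputation
uncertainty in dosages, or a second postprandial time point. Recovery of a
configured effect here validates the estimators' algebra and calibration,
not their robustness to everything real data do.

# Numerical choices and edge cases

* Degenerate Deming fits (`sxy = 0`, zero fasting variance, < 3 complete
  pairs) are skipped and logged, never silently imputed.
* A perfect first stage (instrument ≡ exposure) caps the weak-instrument F
  at 10¹² and leaves the DWH test undefined (NA) — there are no stage-1
  residuals to test with.
* A constant outcome returns a zero IV effect with p = 1 rather than 0/0.
* Near-constant squared residuals (total SS below 10⁻¹² of the squared-norm
  scale) short-circuit the BP statistic to 0: floating-point dust is not
  heteroskedasticity.
* Paired t-tests with zero-variance differences are flagged; an identically
  zero difference reports t = 0, p = 1 ("no change"), a constant nonzero
  shift reports NA ("undefined t, certain change").
* `cutree` cuts at height ≤ h; correlations over pairwise-complete
  observations; undefined correlations (constant traits) are treated as
  independence.
* All generator stages consume seeds derived from one config seed, kept
  below 2³¹; identical config + seed gives byte-identical output.

# Known limitations

* Observational SEs under sampling weights are precision-weight SEs (the
  field's standard `glm(weights=)` behavior), not design-based; with highly
  variable weights their coverage would drift.
* The obs-vs-MR z-test treats the two estimates as independent although they
  share a sample — the usual approximation, documented as such.
* The bivariate QC rule and the clustering representative rule are package
  decisions standing in for undocumented reference-tool internals; both are
  parameterized.
* The multiplicity estimate is computed on the pooled three-state transformed
  matrix; with very small cohorts Spearman correlations are noisy and the
  effective-test count fluctuates accordingly.
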
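# postprandialMR

Estimating the effect of body mass index (BMI) on blood metabolites in three
dietary states — **fasting**, **postprandial** (150 min after a standardized
liquid mixed meal), and **meal response** — with paired observational and
one-sample Mendelian randomization (MR) analyses.

The package is aimed at epidemiologists analyzing meal-challenge metabolomics
in cohorts with a two-subpopulation design (one random sample, one
oversampled for BMI > 27, reconciled by sampling weights). Because
individual-level data of this kind are access-restricted, the package also
ships a calibrated synthetic-cohort generator so that the entire pipeline is
testable, end to end, without restricted data.

## What it computes

For each metabolite trait and state, two effect estimates in rank-normalized
SD units per BMI unit (kg/m²):

* **Observational:** weighted least squares,
  `metabolite ~ visit_date + subpopulation + age + sex + bmi`, with
  Breusch–Pagan homoskedasticity p and sequential (type I) η² for the model
  and for BMI.
* **MR (2SLS):** stage 1 `bmi ~ pgs + covariables`, stage 2
  `metabolite ~ fitted(bmi) + covariables`, with proper 2SLS standard errors
  (residuals formed with the observed exposure), the weak-instrument partial
  F, and the Durbin–Wu–Hausman endogeneity test. The instrument is a
  weighted polygenic score, `PGS_i = Σ_j w_j d_ij`, built after harmonizing
  GWAS effect-allele weights to the cohort (allele matching with swap
  recovery, folded-MAF guard ±0.1, positive alignment).

The **response** phenotype is the vector of vertical residuals from a
per-trait Deming (errors-in-both-variables) regression of postprandial on
fasting abundance,

```
slope = [syy − λ·sxx + sqrt((syy − λ·sxx)² + 4λ·sxy²)] / (2·sxy),  λ = 1,
```

so positive response values mean a larger postprandial rise than the fasting
level predicts. Supporting machinery: metabolite QC (zeros→NA, 10-IQR
univariate fence, bivariate fasting/postprandial outlier removal,
missingness filters), rank-based inverse-normal transformation with seeded
random tie-breaking, principal-variable clustering to estimate the effective
number of independent tests (Bonferroni threshold `α / n_eff`), and
state/sex/framework comparison utilities (z tests, estimate-vector
correlation, shared/unique association counts, lipoprotein profile tables).

## Worked example

```r
library(postprandialMR)

cfg <- synth_config(n_random = 400, n_oversampled = 1100, n_snps = 60,
                    n_metabolites = 24, n_classes = 6, seed = 42)
sim <- simulate_cohort(cfg)        # genotypes, GWAS weights, BMI, metabolites
run <- run_pipeline(sim)           # QC -> response -> RINT -> PGS -> models
print(run)
```

```
pipeline run [wNEO]: 1500 individuals, 24 traits x 3 states
  effective tests: 59 (threshold 0.000847)
  obs-vs-MR overall Pearson r: 0.810
```

The run analyzed 1500 individuals after QC, fitted 24 traits in each of the
three states under both frameworks, estimated 59 effective independent tests
from the pooled transformed trait matrix (so the study-wide threshold is
0.05/59), and found the observational and MR beta vectors strongly
correlated — the qualitative signature of a causal BMI→metabolite pathway.
Top observational associations:

```r
obs <- run$observational
head(obs[order(obs$p), c("trait","state","beta","se","p","eta2_bmi")], 5)
```

```
  trait        state   beta     se        p eta2_bmi
 met007 postprandial 0.0836 0.0084 1.60e-22   0.0610
 met013 postprandial 0.0839 0.0085 2.95e-22   0.0606
 met023     response 0.0850 0.0088 1.50e-21   0.0582
 met011     response 0.0804 0.0085 1.10e-20   0.0557
 met013      fasting 0.0818 0.0088 5.07e-20   0.0537
```

`met007` was generated as a response-effect trait with β = 0.08 SD per BMI
unit; the pipeline recovers it (and shows the expected echo of response
effects in the postprandial cross-section). Each estimate's η² gives the
share of trait variance attributable to BMI after the covariables (~5–6%
here). The MR table carries the same traits with diagnostics:

```r
head(run$mr[order(run$mr$p_iv),
            c("trait","state","beta_iv","se_iv","p_iv","f_stat")], 3)
```

```
  trait        state beta_iv  se_iv     p_iv f_stat
 met018 postprandial  0.1838 0.0298 7.17e-10  178.0
 met023     response  0.1678 0.0273 8.03e-10  179.4
 met021 postprandial  0.1535 0.0268 1.01e-08  184.6
```

First-stage F ≈ 180 rules out weak-instrument concerns; MR standard errors
are ~3× the observational ones, as expected for an instrument explaining
~4.5% of BMI variance.

Sensitivity variants (`unweighted`, `subpop_random`, `subpop_oversampled`,
`female`, `male`, `untransformed`, `extra_covariables`) are one argument
away: `run_pipeline(sim, analysis_tag = "female")`, or run them all with
`run_sensitivity_suite(sim)`.

A file-based interface is provided in `inst/cli/postprandialMR.R`
(subcommands `simulate` and `run-all`, TSV in/out).

## Design notes

See the methods vignette (`vignettes/methods.Rmd`) for the models, the
synthetic world's calibration (why the generator uses a latent
errors-in-both-variables structure with unit-variance states), numerical
edge-case policy, and known limitations.
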
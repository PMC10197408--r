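# rifineq

Measuring and decomposing household income-related inequality in binary
physical-functional-disability outcomes (ADL, IADL, mobility) across
multi-country ageing surveys.

The package is aimed at health-inequality and ageing researchers who work
with harmonized survey microdata: it provides the full analysis chain —
design-weighted, age-post-stratified prevalence; the Erreygers generalized
concentration index; a recentred-influence-function (RIF) regression
decomposition into individual and country-level contributors; and
chained-equation imputation with Rubin pooling — together with a synthetic
multi-country survey generator with known ground-truth inequality, so that
every stage is testable without restricted cohort files.

## The statistic at the core

For a binary outcome *h*, per-capita household income *y*, weights *w* and
weighted fractional income ranks *R* (block-midpoint under ties), the
Erreygers generalized concentration index is

    E = 4 μ C / (b − a) = 8 cov_w(h, R) / (b − a),     C = 2 cov_w(h, R) / μ

with bounds (a, b) = (0, 1) for binary outcomes. E is zero under no
inequality, lies in [−1, 1], and satisfies the mirror condition
E(h) = −E(1−h) that the standard index C violates for bounded outcomes;
negative values indicate pro-poor concentration (the disability burden
falls on the poor). Its recentred influence function

    RIF_i = 4 h_i (2 R_i − 1) + 8 (s_i − A)

(weighted mean exactly E) supplies standard errors and, regressed on
covariates with a country random intercept, the decomposition of the index.

## Worked example

```r
library(rifineq)
cfg   <- generator_config(seed = 42)      # 6 countries x 2000 persons
study <- generate_survey(cfg)
micro <- study$microdata

overall_index(micro, "adl")
#> Erreygers concentration index: -0.0857 (SE 0.0077, 95% CI -0.1008 to -0.0705), n = 12000

head(country_indices(micro, "adl"), 3)
#>   country_code domain    n       index         se      ci_low     ci_high
#> 1          C01    adl 2000 -0.05198148 0.01823459 -0.08772062 -0.01624233
#> 2          C02    adl 2000 -0.10275155 0.01977703 -0.14151383 -0.06398927
#> 3          C03    adl 2000 -0.09833692 0.01864545 -0.13488134 -0.06179251

head(prevalence_table(micro, study$reference_ages, domains = "adl"), 3)
#>   domain country_code group    n prevalence   ci_low  ci_high
#> 1    adl          C01   C01 2000   16.39399 14.61519 18.34277
#> 2    adl          C02   C02 2000   18.21816 16.63557 19.91534
#> 3    adl          C03   C03 2000   15.75795 14.15020 17.51113
```

The overall index of −0.0857 says ADL disability is concentrated among the
poor across the pooled countries; the per-country table shows the spread of
that inequality (here −0.052 to −0.103), and the prevalence table gives the
age-standardised burden per country in percent with design-based 95% CIs.
`decompose_inequality(micro, study$macro, "adl")` then attributes the index
to covariates — in this synthetic study the 85+ age band carries a positive
(inequality-increasing) coefficient of about 0.099 (p ≈ 0.02), while most
other terms are indistinguishable from zero at this sample size.

## The analysis workflow

Numbered drivers under `analysis/` run the study end to end, writing tables
under `results/`:

1. `01_simulate.R` — synthetic study (6 countries × 2000 persons, 10%
   missingness in explanatory variables) to `results/data/`.
2. `02_prevalence.R` — post-stratified prevalence by country and income
   quintile; quintile percentage differences.
3. `03_inequality.R` — per-country and overall Erreygers indices.
4. `04_decompose.R` — chained-equation imputation (m = 5), pooled two-level
   RIF decomposition per domain.

`run_pipeline(pipeline_config(...))` performs the same stages in one call
with a JSON run manifest; `pipeline_config_from_yaml()` reads the
configuration from YAML. The methods vignette
(`vignettes/income-inequality-decomposition.Rmd`) documents the model,
defaults, numerical conventions and limitations.

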
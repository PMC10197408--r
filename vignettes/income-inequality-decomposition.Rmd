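---
title: "Measuring and decomposing income-related inequality in binary disability outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and decomposing income-related inequality in binary disability outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Ageing surveys measure physical functional disability — any difficulty with
activities of daily living (ADL), instrumental activities (IADL), or
mobility — as binary indicators, and disability is consistently more common
among poorer households. `rifineq` implements a complete workflow for
quantifying that income-related inequality across countries and attributing
it to individual and country-level factors:

1. design-weighted, age-post-stratified prevalence with 95% CIs;
2. the Erreygers generalized concentration index over weighted fractional
   income ranks, per country and overall;
3. a recentred-influence-function (RIF) regression decomposition of the
   index with a pooled two-level model;
4. chained-equation imputation of incomplete explanatory variables, with
   Rubin pooling;
5. a synthetic multi-country survey generator with *known* ground-truth
   inequality, so every stage can be validated without restricted survey
   files.

# The inequality measure

Let $h_i \in \{0,1\}$ be the disability indicator, $y_i$ per-capita
household income, $w_i$ the sampling weight, and $R_i$ the weighted
fractional rank of $y_i$: sorting by income, a block of tied incomes gets
the single rank $(W_{<} + W_{=}/2)/W$. This block-midpoint convention makes
the weighted mean of $R$ exactly $1/2$ and keeps the identities below exact
under ties.

The standard concentration index is $C = 2\,\mathrm{cov}_w(h, R)/\mu$ with
$\mu$ the weighted mean of $h$. For binary outcomes $C$ violates the mirror
condition — inequality in attainments does not equal minus inequality in
shortfalls — so the package's headline measure is the Erreygers generalized
index for outcomes bounded in $(a, b)$:

$$E = \frac{4\mu C}{b-a} = \frac{8\,\mathrm{cov}_w(h, R)}{b-a},$$

which satisfies $E(h) = -E(1-h)$ exactly, lies in $[-1, 1]$ for binary $h$,
and is zero when outcome and income rank are independent. Negative values
are *pro-poor* inequality: the disability is concentrated among the poor.

# RIF and decomposition

With $A = \sum_i w_i h_i R_i / W$ and the upper-tail outcome share
$s_i = \sum_j w_j h_j (1\{y_j > y_i\} + \tfrac12 1\{y_j = y_i\})/W$, the
recentred influence function of $E$ (binary bounds) is

$$\mathrm{RIF}_i = 4 h_i (2R_i - 1) + 8 (s_i - A).$$

Its weighted mean equals $E$ exactly, and multiplying one weight $w_i$ by
$1+\varepsilon$ moves the index by
$\varepsilon\, w_i(\mathrm{RIF}_i - E)/W + O(\varepsilon^2)$ — the tests
verify both, including the quadratic decay of the linearization residual.
The analogous expression for the standard index and the linkage
$\mathrm{RIF}^E_i = 4\mu\,\mathrm{RIF}^C_i + 4C(h_i - \mu)$ are implemented
and cross-checked numerically. Index standard errors are the weighted RIF
standard deviation over $\sqrt n$.

The decomposition regresses the RIF on explanatory variables. RIFs are
computed *within country*, against each country's own ranks and index; the
regression then pools countries. This is the only construction under which
country-level covariates — constant within a country — are meaningful, and
it makes the overall index equal the survey-weighted average of country
indices (a pooled-ranks alternative is available via
`overall_index(ranks = "pooled")`). Because the linear model's fitted mean
is the weighted RIF mean, coefficients read as associations between group
membership and the level of the index.

The default model is a linear mixed model with a country random intercept,
fitted by REML with sampling weights as analytic weights; if the
random-intercept variance collapses to the boundary the fit falls back to
weighted least squares with country-cluster-robust standard errors, and the
fallback is recorded. p-values are two-sided Wald z, the convention of
standard mixed-model software. The intercept-only regression identity
(coefficient $=$ index) holds exactly under the WLS/cluster-robust model,
which is why the identity check uses `model = "cluster-robust"`; the
random-intercept fit shrinks toward an unweighted country-mean average and
reproduces the identity only approximately.

Covariate coding follows the conventional reference levels: age band 55–59
(seven 5-year bands, 85+ open), male, married, less-than-upper-secondary
education, and quartile 1 of each of six country-level macro indicators
(hospital beds per 1000, safely managed sanitation %, rural population %,
health expenditure % of GDP, tertiary enrolment %, GDP), giving 31
non-intercept columns. When the number of countries is small relative to
the 18 macro-quartile dummies, some country-level columns are necessarily
collinear; `decompose_inequality()` drops them before fitting and lists
them in `dropped_terms`. At the desk-scale default of 6 countries only the
first macro block is identifiable; with 20+ countries most survive.

# Prevalence estimation

Prevalence is the weighted mean of the 0/1 outcome in percent. Weights are
first post-stratified within country so weighted age-band shares match a
reference age composition exactly (single margin, multiplicative band
factors, country totals preserved — hence idempotent). Variance uses Taylor
linearization of the ratio estimator with clusters as PSUs within strata
(with-replacement approximation); a single-cluster stratum triggers a
logged fallback to the weighted SRS variance. The 95% interval is Wald on
the logit scale, back-transformed — a deliberate choice, since no interval
method is canonical here — and degenerates at all-0/all-1 samples. Missing
outcomes are dropped listwise per domain; only explanatory variables are
ever imputed.

Income quintiles are assigned within country from the weighted empirical
CDF with right-closed intervals: a person joins the lowest quintile whose
upper cut point is at least their income. Exact ties — in particular all
members of one household, who share the household per-capita income —
always share a quintile, so a heavy boundary observation can displace a
20% share by up to its own weight; that is the documented boundary
behaviour. Country quartiles of macro indicators use the same construction,
unweighted, with ties sharing the lower quartile.

# Chained-equation imputation

`impute_chained()` fills missing explanatory cells only (outcomes and
income must be complete). After initializing from observed marginals,
variables are visited in order of increasing missingness each cycle; each
conditional model regresses the target on the other explanatory variables
plus age band and country (fixed dummies). Families: logistic for binary,
multinomial for categorical, predictive mean matching (k = 5 donors) for
continuous. Logistic and PMM steps draw coefficients from the approximate
normal posterior before predicting; the multinomial step samples categories
from the fitted class probabilities without a parameter draw — a documented
simplification. Defaults m = 5, cycles = 10, k = 5 (none is prescribed by
the problem; these are conventional values). A conditional model that
cannot be fitted falls back to a marginal draw for that cycle and the event
is logged. Observed cells are never altered, and identical seeds give
identical completed data.

# What the generator emulates — and what it does not

`generator_config()` defaults define the study conditions once:

* 6 countries, two per income tier (`lower-middle`, `upper-middle`,
  `high`); 33 supported. 2000 persons per country.
* Households of size 1–3 (probabilities 0.30/0.50/0.20) with lognormal
  income (sdlog 0.8) around tier medians 2000/8000/30000; per-capita income
  is household income over size, shared within the household.
* Two strata × 20 clusters per country; the weight is the inverse of the
  stratum inclusion probability (0.9/0.6) times a per-cluster inclusion
  probability drawn uniformly from 0.4–0.9. Age-band sampling is skewed
  young (probabilities 0.32…0.04) and *not* corrected in the weights, so
  post-stratification to the reference shares (0.25, 0.21, 0.17, 0.13,
  0.10, 0.08, 0.06 — a synthetic stand-in for a global 55+ composition) is
  non-vacuous by construction.
* Outcomes: rank-linear mode draws
  $h \sim \mathrm{Bern}(p_0 + b(R - 1/2))$, clipped to $[0.01, 0.99]$ with
  a warning (clipping invalidates the closed form). Without clipping the
  population Erreygers index is $8b\,\mathrm{Var}(R) = 2b/3$, the
  ground-truth anchor of the validation suite. Defaults
  $p_0 = (0.166, 0.176, 0.578)$ and $b = (-0.129, -0.145, -0.206)$ place
  prevalence and the implied indices ($2b/3 \approx -0.086, -0.097,
  -0.137$) on the scale reported for harmonized multi-country ageing
  cohorts. A logistic mode adds age, education, chronic-disease and
  country-intercept structure instead.
* Covariate marginals (gender, marital by age, education rising with
  income rank and tier, chronic disease rising with age, smoking,
  drinking) are plausible but deliberately uncalibrated — no public
  joint distribution exists to calibrate against.

Passing tests on these data therefore demonstrate the *estimators*
(unbiasedness, exact identities, closed-form recovery, imputation sanity),
not the substantive covariate structure of any real cohort: real surveys
have informative nonresponse, panel attrition, item-specific skip patterns
and cohort-specific instruments (e.g. a cohort lacking the mobility block
entirely, representable here as an all-missing outcome column) that the
generator does not model.

# Numerical choices and degenerate inputs

* Tie handling everywhere is block-midpoint; it makes mean-RIF and mirror
  identities exact, not just asymptotic.
* Weighted covariance uses probability-normalized weights; indices are
  survey-weighted by default with an unweighted switch.
* Post-stratification errors (naming the band) when a band has positive
  reference share but no sampled weight; quintiles error with fewer than 5
  distinct incomes; quartiles require 4+ countries; the percentage
  difference $((Q_1 - Q_5)/Q_1)\times 100$ is undefined at $Q_1 = 0$.
* Rank-deficient design matrices are an error listing aliased columns at
  the fitting level; the decomposition wrapper pre-drops collinear
  country-level dummies (recorded) because they are structural at small
  country counts.
* Indices print at four decimals, percentages at one, matching the
  reporting precision conventional for these quantities.

# Validation problem sizes

The test suite checks exact identities on hundreds of random small samples
(n ≤ 200), closed-form index recovery at one country × 50 000 persons
(tolerance 0.015 around $2b/3$), coefficient recovery at 20 countries ×
500 persons (3 SEs), prevalence unbiasedness and interval coverage over 200
replicates of n = 2000, and imputation sanity at 10 countries × 2000 with
20% MCAR and m = 5 — sizes chosen to keep Monte-Carlo error well inside the
stated tolerances while the whole suite runs in well under a minute.

# Known limitations

* Country indices at 2000 persons carry standard errors around 0.008; the
  desk-scale default cannot resolve index differences much below 0.02.
* The between/within ambiguity of pooling (random vs fixed country
  effects) is resolved by the random-intercept default with an explicit
  cluster-robust alternative; with 6 countries the random-intercept
  variance is weakly identified and the fallback is common.
* No replicate-weight variance, no Wagstaff normalization or extended
  (ν-parameter) indices, no concentration-curve dominance tests, and no
  figure rendering.
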
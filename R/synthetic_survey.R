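#' @keywords internal
"_PACKAGE"

#' Age bands used throughout the package
#'
#' Five-year closed bands from 55 with an open 85+ band.
#' @export
age_bands <- function() {
  c("55-59", "60-64", "65-69", "70-74", "75-79", "80-84", "85+")
}

#' Configuration for the synthetic multi-country survey generator
#'
#' Bundles and validates the parameters of the synthetic ageing-survey
#' generator.  Defaults describe a desk-scale study: 6 countries (two per
#' World-Bank-style income tier) of 2000 persons each, household per-capita
#' incomes lognormal around tier-specific medians, a two-stage
#' stratum-by-cluster design with unequal cluster inclusion, and binary
#' disability outcomes whose probability falls linearly in the within-country
#' income rank.  The default rank slopes imply population Erreygers indices
#' (2b/3) of about -0.086 (ADL), -0.097 (IADL) and -0.137 (mobility), and
#' the default baseline prevalences are 16.6%, 17.6% and 57.8%.
#'
#' @param n_countries number of countries (>= 1).
#' @param country_tiers character vector of length `n_countries` with values
#'   in `lower-middle`, `upper-middle`, `high`; default cycles two countries
#'   per tier.
#' @param persons_per_country persons sampled per country (>= 50).
#' @param dgp_mode `"rank-linear"`: P(outcome | rank R) = p0 + b(R - 1/2),
#'   clipped to \[0.01, 0.99\] (a warning is attached when clipping occurs,
#'   since the closed-form index target 2b/3 is then invalid);
#'   `"logistic"`: logit P = qlogis(p0) + age effects + beta_rank (R - 1/2)
#'   + beta_edu + beta_chronic + a country intercept.
#' @param p0 named baseline probabilities per domain (adl, iadl, mobility).
#' @param rank_slope named rank slopes b per domain (rank-linear mode).
#' @param logit_coef list of logistic-mode coefficients: `rank`, `age`
#'   (length-7 band offsets), `edu` (length-3), `chronic`, `country_sd`.
#' @param missing_rate fraction in \[0, 1) of eligible cells set missing by
#'   [inject_missingness()].
#' @param missing_mechanism `"MCAR"` or `"MAR-age"` (rate rises with age band).
#' @param missing_vars explanatory columns eligible for missingness; outcomes
#'   and income are never made missing.
#' @param n_strata,clusters_per_stratum sampling design shape per country.
#' @param household_size_probs probabilities of household sizes 1, 2, 3.
#' @param tier_income_median named per-capita-scale household income medians.
#' @param income_sdlog lognormal sd of household income (log scale).
#' @param age_sample_probs sampling probabilities of the 7 age bands;
#'   deliberately skewed young relative to [reference_age_structure()] so
#'   post-stratification is non-vacuous.
#' @param seed integer RNG seed; all generator output is a deterministic
#'   function of the config.
#' @return validated list of class `generator_config`.
#' @export
generator_config <- function(n_countries = 6,
                             country_tiers = NULL,
                             persons_per_country = 2000,
                             dgp_mode = c("rank-linear", "logistic"),
                             p0 = c(adl = 0.166, iadl = 0.176, mobility = 0.578),
                             rank_slope = c(adl = -0.129, iadl = -0.145,
                                            mobility = -0.206),
                             logit_coef = list(rank = -1.2,
                                               age = c(0, 0.35, 0.7, 0.95, 1.25,
                                                       1.7, 2.3),
                                               edu = c(0, -0.3, -0.8),
                                               chronic = 0.8,
                                               country_sd = 0.3),
                             missing_rate = 0.1,
                             missing_mechanism = c("MCAR", "MAR-age"),
                             missing_vars = c("marital", "education", "chronic",
                                              "smoke", "drink"),
                             n_strata = 2,
                             clusters_per_stratum = 20,
                             household_size_probs = c(0.30, 0.50, 0.20),
                             tier_income_median = c("lower-middle" = 2000,
                                                    "upper-middle" = 8000,
                                                    "high" = 30000),
                             income_sdlog = 0.8,
                             age_sample_probs = c(0.32, 0.24, 0.16, 0.11,
                                                  0.08, 0.05, 0.04),
                             seed = 1L) {
  dgp_mode <- match.arg(dgp_mode)
  missing_mechanism <- match.arg(missing_mechanism)
  tiers <- c("lower-middle", "upper-middle", "high")
  if (is.null(country_tiers)) {
    country_tiers <- rep(tiers, each = 2, length.out = n_countries)
  }
  if (length(country_tiers) != n_countries)
    stop("generator_config: country_tiers must cover all countries")
  if (!all(country_tiers %in% tiers))
    stop("generator_config: unknown tier in country_tiers")
  if (persons_per_country < 50)
    stop("generator_config: persons_per_country must be >= 50")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("generator_config: missing_rate must be in [0, 1)")
  stopifnot(all(c("adl", "iadl", "mobility") %in% names(p0)),
            all(c("adl", "iadl", "mobility") %in% names(rank_slope)),
            length(age_sample_probs) == 7L,
            abs(sum(household_size_probs) - 1) < 1e-9)
  cfg <- list(n_countries = n_countries,
              country_tiers = country_tiers,
              persons_per_country = persons_per_country,
              dgp_mode = dgp_mode, p0 = p0, rank_slope = rank_slope,
              logit_coef = logit_coef,
              missing_rate = missing_rate,
              missing_mechanism = missing_mechanism,
              missing_vars = missing_vars,
              n_strata = n_strata,
              clusters_per_stratum = clusters_per_stratum,
              household_size_probs = household_size_probs,
              tier_income_median = tier_income_median,
              income_sdlog = income_sdlog,
              age_sample_probs = age_sample_probs / sum(age_sample_probs),
              seed = as.integer(seed))
  class(cfg) <- "generator_config"
  cfg
}

#' Reference age composition for post-stratification
#'
#' A synthetic stand-in for a global 55-plus population age composition of
#' the kind published in world population prospect tables: monotonically
#' decreasing shares over the seven age bands, summing to one.  It is a
#' fixed reference distribution, not an empirical estimate.
#'
#' @return data frame with columns `age_band`, `share`.
#' @export
reference_age_structure <- function() {
  data.frame(age_band = age_bands(),
             share = c(0.25, 0.21, 0.17, 0.13, 0.10, 0.08, 0.06),
             stringsAsFactors = FALSE)
}

#' Generate synthetic multi-country survey microdata
#'
#' Simulates person-level ageing-survey microdata with a known ground-truth
#' income-disability gradient.  Households (sizes 1-3) carry a lognormal
#' income with a tier-specific median; per-capita income is the household
#' income divided by household size and is identical within a household.
#' Each household falls in one stratum and one cluster of a two-stage
#' design; the sampling weight is the inverse of the product of the stratum
#' and cluster inclusion probabilities, so weights are strictly positive and
#' shared within a household.  Age bands are sampled with probabilities that
#' deliberately over-represent the young relative to
#' [reference_age_structure()].  Binary ADL, IADL and mobility outcomes are
#' drawn from the configured data-generating mode; in rank-linear mode with
#' no clipping, the population Erreygers index of each domain is 2b/3.
#'
#' @param config a [generator_config()].
#' @return data frame (one row per person) with columns `person_id`,
#'   `country_code`, `household_id`, `stratum_id`, `cluster_id`,
#'   `sample_weight`, `age_years`, `age_band`, `gender`, `marital`,
#'   `education`, `chronic`, `smoke`, `drink`, `income_pc`, `adl`, `iadl`,
#'   `mobility`.  Deterministic given `config$seed`; an attribute
#'   `clipped` records whether rank-linear probabilities were clipped.
#' @export
generate_microdata <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  bands <- age_bands()
  edu_levels <- c("less than upper secondary",
                  "upper secondary and vocational training", "tertiary")
  tier_drink <- c("lower-middle" = 0.30, "upper-middle" = 0.40, "high" = 0.50)
  out <- vector("list", config$n_countries)
  clipped_any <- FALSE
  for (k in seq_len(config$n_countries)) {
    cc <- sprintf("C%02d", k)
    tier <- config$country_tiers[k]
    npers <- config$persons_per_country

    # households until the person quota is met; last household truncated
    hh_sizes <- sample(1:3, ceiling(npers / 1.5) + 8, replace = TRUE,
                       prob = config$household_size_probs)
    cum <- cumsum(hh_sizes)
    n_hh <- which(cum >= npers)[1L]
    hh_sizes <- hh_sizes[seq_len(n_hh)]
    hh_sizes[n_hh] <- hh_sizes[n_hh] - (cum[n_hh] - npers)

    hh_stratum <- sample(seq_len(config$n_strata), n_hh, replace = TRUE)
    hh_cluster <- sample(seq_len(config$clusters_per_stratum), n_hh,
                         replace = TRUE)
    hh_income <- stats::rlnorm(n_hh,
                               meanlog = log(config$tier_income_median[[tier]]),
                               sdlog = config$income_sdlog)
    # inclusion probabilities: stratum-level and cluster-level
    pi_s <- seq(0.9, 0.6, length.out = config$n_strata)
    pi_c <- matrix(stats::runif(config$n_strata * config$clusters_per_stratum,
                                0.4, 0.9),
                   nrow = config$n_strata)
    hh_weight <- 1 / (pi_s[hh_stratum] *
                        pi_c[cbind(hh_stratum, hh_cluster)])

    idx <- rep(seq_len(n_hh), hh_sizes)
    band_i <- sample(seq_along(bands), npers, replace = TRUE,
                     prob = config$age_sample_probs)
    age_lo <- c(55, 60, 65, 70, 75, 80, 85)[band_i]
    age_hi <- c(59, 64, 69, 74, 79, 84, 94)[band_i]
    age <- age_lo + floor(stats::runif(npers) * (age_hi - age_lo + 1))

    income_pc <- hh_income[idx] / hh_sizes[idx]
    R <- fractional_rank(income_pc, hh_weight[idx])

    gender <- ifelse(stats::runif(npers) < 0.55, "female", "male")
    marital <- ifelse(stats::runif(npers) <
                        pmax(0.4, 0.85 - 0.05 * (band_i - 1)),
                      "married", "other")
    p_tert <- pmin(0.9, 0.05 + 0.25 * R +
                     0.15 * (tier == "high") + 0.05 * (tier == "upper-middle"))
    p_mid <- pmin(1 - p_tert, 0.25 + 0.15 * R)
    u <- stats::runif(npers)
    education <- ifelse(u < p_tert, edu_levels[3L],
                        ifelse(u < p_tert + p_mid, edu_levels[2L],
                               edu_levels[1L]))
    chronic <- stats::rbinom(npers, 1L, pmin(0.9, 0.35 + 0.06 * (band_i - 1)))
    smoke <- stats::rbinom(npers, 1L, 0.20)
    drink <- stats::rbinom(npers, 1L, tier_drink[[tier]])

    outc <- list()
    for (dom in c("adl", "iadl", "mobility")) {
      if (config$dgp_mode == "rank-linear") {
        p <- config$p0[[dom]] + config$rank_slope[[dom]] * (R - 0.5)
        if (any(p < 0.01 | p > 0.99)) {
          clipped_any <- TRUE
          p <- pmin(pmax(p, 0.01), 0.99)
        }
      } else {
        lc <- config$logit_coef
        edu_i <- match(education, edu_levels)
        cty_int <- stats::rnorm(1L, 0, lc$country_sd)
        eta <- stats::qlogis(config$p0[[dom]]) + lc$age[band_i] +
          lc$rank * (R - 0.5) + lc$edu[edu_i] + lc$chronic * chronic + cty_int
        p <- stats::plogis(eta)
      }
      outc[[dom]] <- stats::rbinom(npers, 1L, p)
    }

    out[[k]] <- data.frame(
      person_id = sprintf("%s_P%05d", cc, seq_len(npers)),
      country_code = cc,
      household_id = sprintf("%s_H%05d", cc, idx),
      stratum_id = hh_stratum[idx],
      cluster_id = hh_cluster[idx],
      sample_weight = hh_weight[idx],
      age_years = age,
      age_band = bands[band_i],
      gender = gender,
      marital = marital,
      education = education,
      chronic = chronic,
      smoke = smoke,
      drink = drink,
      income_pc = income_pc,
      adl = outc$adl, iadl = outc$iadl, mobility = outc$mobility,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (clipped_any) {
    warning("generate_microdata: rank-linear probabilities were clipped to ",
            "[0.01, 0.99]; the closed-form index target 2b/3 is invalid")
  }
  attr(res, "clipped") <- clipped_any
  res
}

#' Generate country-level macro indicators
#'
#' One row per country with six macro indicators (hospital beds per 1000,
#' safely managed sanitation %, rural population %, current health
#' expenditure % of GDP, tertiary gross enrolment %, GDP per capita scale)
#' whose means track the country income tier, so tier-level contrasts exist
#' by construction.  Deterministic given the config seed.
#'
#' @param config a [generator_config()].
#' @return data frame with `country_code`, `tier` and the six indicators.
#' @export
generate_macro <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed + 1L)
  k <- config$n_countries
  tier <- config$country_tiers
  ti <- match(tier, c("lower-middle", "upper-middle", "high"))
  clamp_pct <- function(x) pmin(99, pmax(1, x))
  data.frame(
    country_code = sprintf("C%02d", seq_len(k)),
    tier = tier,
    hospital_beds_per_1000 = pmax(0.2, c(1.5, 3.5, 5.5)[ti] +
                                    stats::rnorm(k, 0, 0.6)),
    sanitation_pct = clamp_pct(c(40, 70, 95)[ti] + stats::rnorm(k, 0, 6)),
    rural_pct = clamp_pct(c(60, 40, 20)[ti] + stats::rnorm(k, 0, 7)),
    health_exp_pct_gdp = pmax(1, c(4, 6, 9)[ti] + stats::rnorm(k, 0, 0.8)),
    tertiary_enrolment_pct = clamp_pct(c(20, 45, 70)[ti] +
                                         stats::rnorm(k, 0, 6)),
    gdp = exp(log(c(2000, 9000, 42000))[ti] + stats::rnorm(k, 0, 0.15)),
    stringsAsFactors = FALSE)
}

#' Inject missingness into explanatory variables
#'
#' Sets eligible explanatory-variable cells to `NA`, never touching outcomes
#' or income.  `MCAR` makes each eligible cell missing independently with
#' probability `rate`; `MAR-age` scales the rate by a factor rising linearly
#' from 0.4 (youngest band) to 1.6 (85+), capped at 0.95, so the missing
#' fraction is monotonically nondecreasing in age.
#'
#' @param data microdata from [generate_microdata()].
#' @param rate missing fraction in \[0, 1).
#' @param mechanism `"MCAR"` or `"MAR-age"`.
#' @param vars eligible columns (explanatory variables only).
#' @param seed RNG seed.
#' @return the microdata with `NA`s injected.
#' @export
inject_missingness <- function(data, rate = 0.1,
                               mechanism = c("MCAR", "MAR-age"),
                               vars = c("marital", "education", "chronic",
                                        "smoke", "drink"),
                               seed = 1L) {
  mechanism <- match.arg(mechanism)
  if (rate < 0 || rate >= 1) stop("inject_missingness: rate must be in [0, 1)")
  forbidden <- intersect(vars, c("adl", "iadl", "mobility", "income_pc",
                                 "sample_weight"))
  if (length(forbidden))
    stop("inject_missingness: outcomes, income and weights stay complete: ",
         paste(forbidden, collapse = ", "))
  if (rate == 0) return(data)
  set.seed(as.integer(seed))
  n <- nrow(data)
  band_i <- match(data$age_band, age_bands())
  cell_rate <- if (mechanism == "MCAR") rep(rate, n)
               else pmin(0.95, rate * (0.4 + 0.2 * (band_i - 1)))
  for (v in vars) {
    miss <- stats::runif(n) < cell_rate
    data[[v]][miss] <- NA
  }
  data
}

#' Generate a complete synthetic study (microdata, macro table, reference ages)
#'
#' Convenience wrapper bundling [generate_microdata()], [generate_macro()]
#' and [reference_age_structure()]; applies [inject_missingness()] when
#' `config$missing_rate > 0` and `missingness = TRUE`.
#'
#' @param config a [generator_config()].
#' @param missingness inject missingness per the config (default `FALSE`).
#' @return list with elements `microdata`, `macro`, `reference_ages`.
#' @export
generate_survey <- function(config, missingness = FALSE) {
  micro <- generate_microdata(config)
  if (missingness && config$missing_rate > 0) {
    micro <- inject_missingness(micro, rate = config$missing_rate,
                                mechanism = config$missing_mechanism,
                                vars = config$missing_vars,
                                seed = config$seed + 2L)
  }
  list(microdata = micro, macro = generate_macro(config),
       reference_ages = reference_age_structure())
}
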
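two_band_data <- function() {
  # weighted age shares (0.8, 0.2) against a (0.5, 0.5) reference
  data.frame(country_code = "C01",
             age_band = c("55-59", "55-59", "60-64"),
             sample_weight = c(40, 40, 20),
             stringsAsFactors = FALSE)
}

two_band_ref <- function() {
  data.frame(age_band = c("55-59", "60-64"), share = c(0.5, 0.5),
             stringsAsFactors = FALSE)
}

test_that("post-stratification matches the worked two-band example", {
  d <- two_band_data()
  w2 <- poststratify_weights(d, two_band_ref())
  # band factors 0.625 and 2.5; total weight 100 preserved
  expect_equal(w2, c(25, 25, 50))
  expect_equal(sum(w2), sum(d$sample_weight))
  sh <- tapply(w2, d$age_band, sum) / sum(w2)
  expect_equal(as.vector(sh), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("post-stratification is a fixed point on matched samples and idempotent", {
  d <- two_band_data()
  d$sample_weight <- c(25, 25, 50)            # already at the reference
  expect_equal(poststratify_weights(d, two_band_ref()), d$sample_weight)
  s <- small_survey(seed = 3)
  once <- poststratify_weights(s$microdata, s$reference_ages)
  d2 <- s$microdata
  d2$sample_weight <- once
  expect_equal(poststratify_weights(d2, s$reference_ages), once,
               tolerance = 1e-12)
})

test_that("post-stratification errors name an unsampled positive-share band", {
  d <- two_band_data()
  ref <- data.frame(age_band = c("55-59", "60-64", "85+"),
                    share = c(0.4, 0.4, 0.2))
  expect_error(poststratify_weights(d, ref), "85\\+")
  expect_error(poststratify_weights(d, two_band_ref()[1, ]), "sum to 1")
})

test_that("weighted prevalence matches direct weighted means and boundaries", {
  expect_equal(weighted_prevalence(c(1, 1, 0, 0))$prevalence, 50)
  expect_equal(weighted_prevalence(c(1, 0), w = c(3, 1))$prevalence, 75)
  z <- weighted_prevalence(rep(0, 5))
  expect_equal(c(z$prevalence, z$ci_low, z$ci_high), c(0, 0, 0))
  expect_error(weighted_prevalence(c(1, NA)), "missing")
  expect_error(weighted_prevalence(c(1, 2)), "0/1")
})

test_that("single-cluster strata trigger the SRS variance fallback", {
  h <- rbinom(40, 1, 0.5)
  expect_warning(
    est <- weighted_prevalence(h, stratum = rep(1:2, each = 20),
                               cluster = c(rep(1:4, 5), rep(1, 20))),
    "single-cluster")
  expect_true(est$ci_low <= est$prevalence & est$prevalence <= est$ci_high)
})

test_that("prevalence estimator is unbiased with near-nominal interval coverage", {
  set.seed(33)
  reps <- 200
  est <- numeric(reps)
  cover <- logical(reps)
  for (r in seq_len(reps)) {
    h <- rbinom(2000, 1, 0.3)
    e <- weighted_prevalence(h)
    est[r] <- e$prevalence
    cover[r] <- e$ci_low <= 30 && 30 <= e$ci_high
  }
  mc_se <- stats::sd(est) / sqrt(reps)
  expect_lt(abs(mean(est) - 30), 3 * mc_se)
  expect_gte(mean(cover), 0.92)
  expect_lte(mean(cover), 0.98)
})

test_that("income quintiles split evenly for distinct incomes and unit weights", {
  d <- data.frame(country_code = "A", income_pc = sample(1:100),
                  sample_weight = 1)
  q <- assign_income_quintiles(d)
  expect_equal(unname(table(q)), rep(20L, 5), ignore_attr = TRUE)
  expect_true(all(tapply(d$income_pc, q, max)[1:4] <
                    tapply(d$income_pc, q, min)[2:5]))
})

test_that("weighted quintiles keep ties together and bound the boundary error", {
  # one heavy person at the top: weighted CDF jumps across quintiles 2-5
  d <- data.frame(country_code = "A", income_pc = 1:5,
                  sample_weight = c(1, 1, 1, 1, 16))
  q <- assign_income_quintiles(d)
  expect_equal(q, c(1L, 1L, 1L, 1L, 2L))
  sh <- tapply(d$sample_weight, q, sum) / sum(d$sample_weight)
  # each realized share within one boundary person's weight of 20%
  expect_true(all(abs(sh - 0.2) <= 16 / 20 + 1e-12))
  # exact ties (household members) share a quintile
  d2 <- data.frame(country_code = "A",
                   income_pc = c(rep(c(10, 20, 30, 40, 50), each = 2)),
                   sample_weight = 1)
  q2 <- assign_income_quintiles(d2)
  expect_true(all(tapply(q2, d2$income_pc, function(x) length(unique(x))) == 1))
  expect_error(assign_income_quintiles(
    data.frame(country_code = "A", income_pc = rep(3, 10),
               sample_weight = 1)), "distinct")
})

test_that("country quartiles follow sorted ranks with ties sharing the lower", {
  m <- data.frame(country_code = paste0("C", 1:8), gdp = 8:1)
  q <- assign_country_quartiles(m, "gdp")
  expect_equal(unname(table(q)), rep(2L, 4), ignore_attr = TRUE)
  m2 <- data.frame(country_code = paste0("C", 1:8),
                   gdp = c(1, 1, 1, 5, 6, 7, 8, 9))
  q2 <- assign_country_quartiles(m2, "gdp")
  expect_equal(unname(q2[1:3]), rep(1L, 3))
  expect_error(assign_country_quartiles(
    data.frame(country_code = paste0("C", 1:3), gdp = 1:3), "gdp"),
    ">= 4 countries")
})

test_that("percentage difference follows its printed formula", {
  expect_equal(percentage_difference(20, 10), 50)
  expect_equal(percentage_difference(10, 10), 0)
  expect_equal(percentage_difference(23.1, 11.8), 48.9177489177,
               tolerance = 1e-9)
  expect_error(percentage_difference(0, 5), "undefined")
})

test_that("quintile prevalence is nonincreasing under a pro-poor gradient", {
  cfg <- generator_config(n_countries = 2, persons_per_country = 8000,
                          seed = 12)
  s <- generate_survey(cfg)
  tab <- prevalence_table(s$microdata, s$reference_ages, domains = "adl",
                          by_quintile = TRUE)
  for (cc in unique(tab$country_code)) {
    p <- tab$prevalence[tab$country_code == cc][order(
      tab$quintile[tab$country_code == cc])]
    # monotone trend up to sampling noise: poorest well above richest
    expect_gt(p[1], p[5])
    expect_lt(stats::cor(seq_len(5), p), 0)
  }
})
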
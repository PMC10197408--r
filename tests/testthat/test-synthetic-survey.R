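test_that("generator configs are validated", {
  expect_error(generator_config(persons_per_country = 20), ">= 50")
  expect_error(generator_config(missing_rate = 1), "missing_rate")
  expect_error(generator_config(n_countries = 3,
                                country_tiers = c("high", "high")),
               "cover all countries")
  expect_error(generator_config(n_countries = 2,
                                country_tiers = c("high", "rich")),
               "unknown tier")
})

test_that("microdata respects schema invariants and household consistency", {
  s <- small_survey(seed = 2, n_countries = 4, persons = 400)
  d <- s$microdata
  expect_silent(validate_microdata(d))
  expect_equal(nrow(d), 1600)
  expect_true(all(d$age_years >= 55))
  expect_true(all(d$sample_weight > 0))
  # per-capita income identical within household
  rng <- tapply(d$income_pc, d$household_id, function(x) max(x) - min(x))
  expect_true(all(rng == 0))
  # weights shared within household
  wrng <- tapply(d$sample_weight, d$household_id, function(x) max(x) - min(x))
  expect_true(all(wrng == 0))
})

test_that("generation is deterministic in the seed and sensitive to it", {
  cfg <- generator_config(n_countries = 2, persons_per_country = 200, seed = 9)
  expect_identical(generate_microdata(cfg), generate_microdata(cfg))
  expect_identical(generate_macro(cfg), generate_macro(cfg))
  cfg2 <- cfg
  cfg2$seed <- 10L
  expect_false(identical(generate_microdata(cfg), generate_microdata(cfg2)))
})

test_that("macro indicators are shaped and tier-ordered by construction", {
  cfg <- generator_config(n_countries = 9,
                          country_tiers = rep(c("lower-middle", "upper-middle",
                                                "high"), each = 3),
                          persons_per_country = 50, seed = 4)
  m <- generate_macro(cfg)
  expect_equal(nrow(m), 9)
  expect_false(anyNA(m))
  expect_true(all(m$sanitation_pct >= 0 & m$sanitation_pct <= 100))
  expect_gt(mean(m$gdp[m$tier == "high"]),
            mean(m$gdp[m$tier == "lower-middle"]))
})

test_that("rank-linear mode recovers its closed-form index 2b/3", {
  # b = 0: outcome independent of rank
  cfg0 <- generator_config(n_countries = 1, persons_per_country = 10000,
                           p0 = c(adl = 0.2, iadl = 0.2, mobility = 0.2),
                           rank_slope = c(adl = 0, iadl = 0, mobility = 0),
                           seed = 1)
  d0 <- generate_microdata(cfg0)
  e0 <- concentration_index(d0$adl, d0$income_pc, d0$sample_weight)
  expect_lt(abs(e0$value), 3 * e0$se)
  # b = 0.3 with p0 = 0.5: no clipping, E -> 2b/3 = 0.2
  cfg <- generator_config(n_countries = 1, persons_per_country = 20000,
                          p0 = c(adl = 0.5, iadl = 0.5, mobility = 0.5),
                          rank_slope = c(adl = 0.3, iadl = 0.3, mobility = 0.3),
                          seed = 7)
  d <- generate_microdata(cfg)
  expect_false(attr(d, "clipped"))
  e <- concentration_index(d$adl, d$income_pc, d$sample_weight)
  expect_lt(abs(e$value - 0.2), 3 * e$se)
  # clipping emits a warning when |b| is too large for p0
  cfgc <- generator_config(n_countries = 1, persons_per_country = 100,
                           p0 = c(adl = 0.05, iadl = 0.5, mobility = 0.5),
                           rank_slope = c(adl = 0.5, iadl = 0, mobility = 0),
                           seed = 3)
  expect_warning(generate_microdata(cfgc), "clipped")
})

test_that("logistic mode produces an age gradient and a pro-poor index", {
  cfg <- generator_config(n_countries = 2, persons_per_country = 5000,
                          dgp_mode = "logistic", seed = 8)
  d <- generate_microdata(cfg)
  young <- d$age_band %in% c("55-59", "60-64")
  expect_gt(mean(d$adl[!young]), mean(d$adl[young]))
  e <- concentration_index(d$adl[d$country_code == "C01"],
                           d$income_pc[d$country_code == "C01"],
                           d$sample_weight[d$country_code == "C01"])
  expect_lt(e$value, 0)
})

test_that("sampled weighted age shares differ from the reference structure", {
  s <- small_survey(seed = 5, n_countries = 2, persons = 2000)
  d <- s$microdata
  sh <- tapply(d$sample_weight, d$age_band, sum) / sum(d$sample_weight)
  ref <- stats::setNames(s$reference_ages$share, s$reference_ages$age_band)
  expect_gt(max(abs(sh - ref[names(sh)])), 0.02)
})

test_that("missingness injection honours rate, mechanism and exclusions", {
  cfg <- generator_config(n_countries = 2, persons_per_country = 10000,
                          seed = 6)
  d <- generate_microdata(cfg)
  expect_identical(inject_missingness(d, rate = 0), d)        # no-op
  m1 <- inject_missingness(d, rate = 0.2, mechanism = "MCAR", seed = 1)
  expect_false(anyNA(m1$adl) || anyNA(m1$income_pc))
  frac <- mean(is.na(m1$education))
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / nrow(d)))   # binomial check
  m2 <- inject_missingness(d, rate = 0.2, mechanism = "MAR-age", seed = 1)
  byband <- tapply(is.na(m2$education), m2$age_band, mean)[age_bands()]
  expect_true(all(diff(byband) > -0.02))  # nondecreasing up to noise
  expect_gt(byband[["85+"]], byband[["55-59"]])
  expect_error(inject_missingness(d, rate = 0.2, vars = "adl"), "complete")
  expect_error(inject_missingness(d, rate = 1), "rate")
})
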
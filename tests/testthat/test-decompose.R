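test_that("design matrix codes references and counts columns as documented", {
  s <- small_survey(seed = 41, n_countries = 8, persons = 400)
  X <- build_design_matrix(s$microdata, s$macro)
  # 6 age + 1 gender + 1 marital + 2 education + 3 lifestyle/chronic
  # + 6 macro x 3 quartile dummies = 31 non-intercept columns
  expect_equal(ncol(X) - 1L, 31L)
  # coding check: a 62-year-old married tertiary-educated male sets exactly
  # the age-60 and tertiary dummies among the individual blocks
  d1 <- s$microdata[1, ]
  d1$age_years <- 62; d1$age_band <- "60-64"; d1$gender <- "male"
  d1$marital <- "married"; d1$education <- "tertiary"
  d1$chronic <- 0; d1$smoke <- 0; d1$drink <- 0
  x <- build_design_matrix(d1, s$macro)[1, ]
  indiv <- x[!grepl("_q|Intercept", names(x))]
  expect_equal(sort(names(indiv[indiv == 1])),
               sort(c("age_band60-64", "educationtertiary")))
  # unseen level errors
  d2 <- s$microdata
  d2$education[1] <- "college"
  expect_error(build_design_matrix(d2, s$macro), "college")
  dm <- s$microdata
  dm$marital[2] <- NA
  expect_error(build_design_matrix(dm, s$macro), "impute")
})

test_that("two-level fit recovers simulated coefficients and flags defects", {
  set.seed(51)
  s <- small_survey(seed = 51, n_countries = 12, persons = 250)
  d <- s$microdata
  X <- build_design_matrix(d, s$macro)
  keep <- sort(qr(X)$pivot[seq_len(qr(X)$rank)])
  X <- X[, keep, drop = FALSE]
  beta <- stats::setNames(stats::runif(ncol(X), -0.3, 0.3), colnames(X))
  u <- stats::rnorm(12, 0, 0.05)
  yy <- drop(X %*% beta) + u[match(d$country_code, unique(d$country_code))] +
    stats::rnorm(nrow(d), 0, 0.4)
  fit <- fit_two_level(yy, X, d$country_code)
  expect_s3_class(fit, "decomposition_result")
  expect_true(all(fit$coefficients$p_value >= 0 & fit$coefficients$p_value <= 1))
  # individual-level coefficients (well identified here) close to truth
  indiv <- !grepl("_q|Intercept", fit$coefficients$term)
  err <- abs(fit$coefficients$estimate - beta)[indiv]
  expect_true(all(err < 4 * fit$coefficients$se[indiv]))
  # rank deficiency errors, naming the aliased column
  X2 <- cbind(X, dup = X[, 2])
  expect_error(fit_two_level(yy, X2, d$country_code), "dup")
})

test_that("intercept-only cluster-robust fit reproduces the index exactly", {
  s <- small_survey(seed = 52)
  d <- s$microdata
  w <- d$sample_weight
  rif <- numeric(nrow(d))
  for (cc in unique(d$country_code)) {
    i <- d$country_code == cc
    rif[i] <- rif_erreygers(d$adl[i], d$income_pc[i], w[i])
  }
  X <- matrix(1, nrow(d), 1, dimnames = list(NULL, "(Intercept)"))
  fit <- fit_two_level(rif, X, d$country_code, weights = w,
                       model = "cluster-robust")
  expect_equal(fit$coefficients$estimate, overall_index(d, "adl")$value,
               tolerance = 1e-12)
})

test_that("Rubin pooling matches its explicit formulas", {
  mk <- function(est, se) {
    out <- list(coefficients = data.frame(term = "x", estimate = est,
                                          se = se, p_value = NA_real_),
                model = "cluster-robust", fallback = FALSE, n_persons = 10,
                n_countries = 2, m_imputations = 1L, pooling = "none")
    class(out) <- "decomposition_result"
    out
  }
  # m = 1: identity
  one <- pool_rubin(list(mk(1.5, 0.3)))
  expect_equal(one$coefficients$estimate, 1.5)
  expect_equal(one$coefficients$se, 0.3)
  # identical coefficients: zero between-variance, pooled SE = within SE
  same <- pool_rubin(list(mk(2, 0.5), mk(2, 0.5)))
  expect_equal(same$coefficients$se, 0.5)
  # m = 5 hand-built set vs spreadsheet-style evaluation
  q <- c(1.0, 1.2, 0.8, 1.1, 0.9)
  u <- c(0.2, 0.25, 0.22, 0.18, 0.21)
  pooled <- pool_rubin(mapply(mk, q, u, SIMPLIFY = FALSE))
  qbar <- mean(q)
  ubar <- mean(u^2)
  B <- stats::var(q)
  Tvar <- ubar + (1 + 1 / 5) * B
  df <- 4 * (1 + ubar / ((1 + 1 / 5) * B))^2
  expect_equal(pooled$coefficients$estimate, qbar)
  expect_equal(pooled$coefficients$se, sqrt(Tvar))
  expect_equal(pooled$coefficients$p_value,
               2 * stats::pt(-abs(qbar / sqrt(Tvar)), df))
  expect_error(pool_rubin(list(mk(1, 1), {
    r <- mk(1, 1); r$coefficients$term <- "y"; r
  })), "mismatched")
})

test_that("end-to-end decomposition pools imputations and drops aliased terms", {
  s <- small_survey(seed = 53)
  d <- inject_missingness(s$microdata, rate = 0.1, seed = 7)
  imp <- impute_chained(d, imputation_schema(m = 2, cycles = 2, seed = 3))
  res <- decompose_inequality(imp, s$macro, "adl")
  expect_equal(res$m_imputations, 2L)
  expect_equal(res$pooling, "Rubin")
  expect_true(length(res$dropped_terms) > 0)   # 6 countries < 18 macro dummies
  expect_true(all(c("educationtertiary", "chronic") %in%
                    res$coefficients$term))
})
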
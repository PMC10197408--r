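#' Design matrix for the RIF decomposition
#'
#' Dummy-codes the individual covariates and the country-level macro
#' quartiles with fixed reference levels: age band 55-59, male, married,
#' less-than-upper-secondary education, no chronic disease / non-smoker /
#' non-drinker, and quartile 1 of each macro indicator.  Age enters as the
#' seven ordered bands (6 dummies); each of the six macro indicators enters
#' as quartile dummies (3 each), giving 31 non-intercept columns.
#'
#' @param data microdata with complete covariates (post-imputation).
#' @param macro country-level macro table; quartiles are computed per
#'   indicator with [assign_country_quartiles()].
#' @param macro_vars macro indicators to include (default all six).
#' @return numeric model matrix including an intercept column, with an
#'   attribute `terms_map` describing each column.  Errors on unseen
#'   category levels.
#' @export
build_design_matrix <- function(data, macro,
                                macro_vars = c("hospital_beds_per_1000",
                                               "sanitation_pct", "rural_pct",
                                               "health_exp_pct_gdp",
                                               "tertiary_enrolment_pct",
                                               "gdp")) {
  edu_levels <- c("less than upper secondary",
                  "upper secondary and vocational training", "tertiary")
  check_levels <- function(x, levels, what) {
    bad <- setdiff(unique(x[!is.na(x)]), levels)
    if (length(bad))
      stop("build_design_matrix: unseen ", what, " level: ",
           paste(bad, collapse = ", "))
    if (anyNA(x))
      stop("build_design_matrix: missing ", what,
           "; impute covariates first")
    factor(x, levels = levels)
  }
  df <- data.frame(
    age_band = check_levels(data$age_band, age_bands(), "age_band"),
    gender = check_levels(data$gender, c("male", "female"), "gender"),
    marital = check_levels(data$marital, c("married", "other"), "marital"),
    education = check_levels(data$education, edu_levels, "education"),
    chronic = as.numeric(data$chronic),
    smoke = as.numeric(data$smoke),
    drink = as.numeric(data$drink))
  for (v in macro_vars) {
    q <- assign_country_quartiles(macro, v)
    qi <- q[match(data$country_code, names(q))]
    if (anyNA(qi))
      stop("build_design_matrix: country without macro quartile for ", v)
    df[[paste0(v, "_q")]] <- factor(qi, levels = 1:4,
                                    labels = paste0("Q", 1:4))
  }
  X <- stats::model.matrix(~ ., df)
  attr(X, "terms_map") <- colnames(X)
  X
}

#' Two-level RIF regression
#'
#' Regresses per-person RIF values of the concentration index on individual
#' and country-level explanatory variables.  The default model is a linear
#' mixed model with a country random intercept, fitted by REML
#' (sampling weights enter as analytic weights); when the random-intercept
#' variance estimate collapses to the boundary the model is refitted as
#' weighted least squares with country-cluster-robust standard errors, and
#' the fallback is recorded.  `model = "cluster-robust"` requests the WLS /
#' cluster-robust fit directly (this is also the model under which an
#' intercept-only fit reproduces the weighted mean of the RIF — the index —
#' exactly).  p-values are two-sided Wald (normal approximation, as in the
#' z-tests of standard mixed-model software).
#'
#' @param rif numeric RIF vector.
#' @param X design matrix including an intercept (see
#'   [build_design_matrix()]); must be full column rank.
#' @param country country identifier per row.
#' @param weights analytic weights (default equal).
#' @param model `"random-intercept"` or `"cluster-robust"`.
#' @return object of class `decomposition_result`: list with `coefficients`
#'   (data frame `term`, `estimate`, `se`, `p_value`), `model` (the model
#'   actually used), `fallback`, `n_persons`, `n_countries`,
#'   `m_imputations` (1), `pooling` ("none").
#' @export
fit_two_level <- function(rif, X, country, weights = NULL,
                          model = c("random-intercept", "cluster-robust")) {
  model <- match.arg(model)
  n <- length(rif)
  stopifnot(nrow(X) == n, length(country) == n)
  if (is.null(weights)) weights <- rep(1, n)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- setdiff(colnames(X), colnames(X)[qrX$pivot[seq_len(qrX$rank)]])
    stop("fit_two_level: design matrix is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  if (length(unique(country)) < 2L && model == "random-intercept")
    model <- "cluster-robust"

  fallback <- FALSE
  if (model == "random-intercept") {
    dat <- data.frame(.rif = rif, .country = factor(country),
                      .w = weights, check.names = FALSE)
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(.rif ~ 0 + X + (1 | .country), data = dat, weights = .w,
                 REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular =
                                               lme4::.makeCC(action = "ignore",
                                                             tol = 1e-4)))))
    if (lme4::isSingular(fit, tol = 1e-4)) {
      fallback <- TRUE
      model <- "cluster-robust"
    } else {
      est <- lme4::fixef(fit)
      se <- sqrt(diag(as.matrix(stats::vcov(fit))))
      names(est) <- sub("^X", "", names(est))
    }
  }
  if (model == "cluster-robust") {
    fit <- stats::lm(rif ~ 0 + X, weights = weights)
    est <- stats::coef(fit)
    names(est) <- sub("^X", "", names(est))
    if (length(unique(country)) >= 2L) {
      V <- sandwich::vcovCL(fit, cluster = factor(country))
    } else {
      V <- sandwich::vcovHC(fit, type = "HC1")
    }
    se <- sqrt(diag(V))
  }
  z <- est / se
  out <- list(coefficients = data.frame(term = names(est),
                                        estimate = unname(est),
                                        se = unname(se),
                                        p_value = 2 * stats::pnorm(-abs(z)),
                                        stringsAsFactors = FALSE),
              model = model, fallback = fallback,
              n_persons = n, n_countries = length(unique(country)),
              m_imputations = 1L, pooling = "none")
  class(out) <- "decomposition_result"
  out
}

#' @export
print.decomposition_result <- function(x, ...) {
  cat(sprintf("RIF decomposition (%s%s): %d persons, %d countries, m = %d\n",
              x$model, if (x$fallback) ", after singular-fit fallback" else "",
              x$n_persons, x$n_countries, x$m_imputations))
  co <- x$coefficients
  co$estimate <- sprintf("%.4f", co$estimate)
  co$se <- sprintf("%.4f", co$se)
  co$p_value <- sprintf("%.4g", co$p_value)
  print(co, row.names = FALSE)
  invisible(x)
}

#' Pool decomposition results across imputations (Rubin's rules)
#'
#' Pooled estimate = mean of the per-imputation estimates; total variance =
#' mean within-imputation variance + (1 + 1/m) x between-imputation
#' variance; degrees of freedom by the classic Rubin formula
#' \eqn{(m-1)(1 + W/((1+1/m)B))^2}; p-values from the t distribution on
#' those df (normal when the between-variance is zero or m = 1).
#'
#' @param results list of `decomposition_result` objects over the same
#'   term set.
#' @return a pooled `decomposition_result` with `pooling = "Rubin"`.
#' @export
pool_rubin <- function(results) {
  m <- length(results)
  if (m < 1L) stop("pool_rubin: need at least one result")
  terms <- results[[1L]]$coefficients$term
  for (r in results) {
    if (!identical(r$coefficients$term, terms))
      stop("pool_rubin: imputations have mismatched term sets")
  }
  if (m == 1L) {
    out <- results[[1L]]
    out$pooling <- "Rubin"
    return(out)
  }
  p_terms <- length(terms)
  Q <- matrix(sapply(results, function(r) r$coefficients$estimate),
              nrow = p_terms)                                  # p x m
  U <- matrix(sapply(results, function(r) r$coefficients$se^2),
              nrow = p_terms)
  qbar <- rowMeans(Q)
  ubar <- rowMeans(U)
  B <- apply(Q, 1L, stats::var)
  Tvar <- ubar + (1 + 1 / m) * B
  se <- sqrt(Tvar)
  p <- numeric(length(qbar))
  for (i in seq_along(qbar)) {
    if (B[i] <= 0) {
      p[i] <- 2 * stats::pnorm(-abs(qbar[i] / se[i]))
    } else {
      df <- (m - 1) * (1 + ubar[i] / ((1 + 1 / m) * B[i]))^2
      p[i] <- 2 * stats::pt(-abs(qbar[i] / se[i]), df)
    }
  }
  out <- list(coefficients = data.frame(term = terms, estimate = qbar,
                                        se = se, p_value = p,
                                        stringsAsFactors = FALSE),
              model = results[[1L]]$model,
              fallback = any(vapply(results, `[[`, TRUE, "fallback")),
              n_persons = results[[1L]]$n_persons,
              n_countries = results[[1L]]$n_countries,
              m_imputations = m, pooling = "Rubin")
  class(out) <- "decomposition_result"
  out
}

#' End-to-end RIF decomposition of income-related inequality
#'
#' For one disability domain: computes within-country income ranks and the
#' per-person Erreygers RIF against each country's own index, builds the
#' covariate design matrix (individual dummies plus country-level macro
#' quartiles), and regresses the pooled RIF vector on it with the two-level
#' model.  With a list of imputed datasets, fits each and pools by Rubin's
#' rules.
#'
#' @param data microdata (complete covariates), or a list of m imputed
#'   microdata sets as returned by [impute_chained()].
#' @param macro country-level macro table.
#' @param domain one of `"adl"`, `"iadl"`, `"mobility"`.
#' @param weighted use sampling weights as analytic weights.
#' @param model passed to [fit_two_level()].
#' @param macro_vars macro indicators to include (see
#'   [build_design_matrix()]).
#' @details Country-level quartile dummies that are collinear across the
#'   observed countries (inevitable when the country count is small relative
#'   to the 18 macro-quartile dummies) are dropped before fitting and listed
#'   in the result's `dropped_terms` element.
#' @return a `decomposition_result` (with `dropped_terms`).
#' @export
decompose_inequality <- function(data, macro,
                                 domain = c("adl", "iadl", "mobility"),
                                 weighted = TRUE,
                                 model = c("random-intercept",
                                           "cluster-robust"),
                                 macro_vars = c("hospital_beds_per_1000",
                                                "sanitation_pct", "rural_pct",
                                                "health_exp_pct_gdp",
                                                "tertiary_enrolment_pct",
                                                "gdp")) {
  domain <- match.arg(domain)
  model <- match.arg(model)
  datasets <- if (is.data.frame(data)) list(data) else data
  dropped <- character(0)
  fits <- lapply(datasets, function(d) {
    keep <- !is.na(d[[domain]])
    d <- d[keep, , drop = FALSE]
    w <- if (weighted) d$sample_weight else rep(1, nrow(d))
    rif <- numeric(nrow(d))
    for (cc in unique(d$country_code)) {
      i <- d$country_code == cc
      rif[i] <- rif_erreygers(d[[domain]][i], d$income_pc[i], w[i])
    }
    X <- build_design_matrix(d, macro, macro_vars = macro_vars)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      keep_i <- sort(qrX$pivot[seq_len(qrX$rank)])
      dropped <<- union(dropped, colnames(X)[-keep_i])
      X <- X[, keep_i, drop = FALSE]
    }
    fit_two_level(rif, X, d$country_code, weights = w, model = model)
  })
  out <- pool_rubin(fits)
  out$dropped_terms <- dropped
  out
}
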
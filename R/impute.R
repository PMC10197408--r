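#' Imputation schema for chained equations
#'
#' Declares which explanatory variables to impute and with which conditional
#' model family: `pmm` (predictive mean matching, continuous), `logistic`
#' (binary) or `multinomial` (categorical with > 2 levels).  With
#' `families = NULL` the family is inferred from the column type.  The
#' visit order is increasing observed missingness, ties broken by column
#' order.
#'
#' @param vars variables eligible for imputation.
#' @param families optional named character vector variable -> family.
#' @param m number of imputed datasets (>= 1).
#' @param cycles chained-equation iterations per imputation (>= 1).
#' @param donors k nearest donors for PMM.
#' @param seed RNG seed.
#' @return list of class `imputation_schema`.
#' @export
imputation_schema <- function(vars = c("marital", "education", "chronic",
                                       "smoke", "drink"),
                              families = NULL, m = 5L, cycles = 10L,
                              donors = 5L, seed = 1L) {
  if (m < 1L) stop("imputation_schema: m must be >= 1")
  if (cycles < 1L) stop("imputation_schema: cycles must be >= 1")
  out <- list(vars = vars, families = families, m = as.integer(m),
              cycles = as.integer(cycles), donors = as.integer(donors),
              seed = as.integer(seed))
  class(out) <- "imputation_schema"
  out
}

infer_family <- function(x) {
  ux <- unique(x[!is.na(x)])
  if (is.numeric(x) && length(ux) > 2L) return("pmm")
  if (length(ux) <= 2L) return("logistic")
  "multinomial"
}

# one conditional draw for the missing cells of a target variable
impute_one <- function(target, df, mis, family, donors, log_env) {
  form <- stats::as.formula(paste0("`", target, "` ~ ."))
  obs <- !mis
  fallback <- function(reason) {
    log_env$log <- c(log_env$log,
                     sprintf("%s: %s; marginal draw used", target, reason))
    sample(df[[target]][obs], sum(mis), replace = TRUE)
  }
  tryCatch({
    if (family == "logistic") {
      y <- df[[target]]
      lv <- sort(unique(y[obs]))
      if (length(lv) < 2L) return(fallback("degenerate observed values"))
      yb <- as.integer(y == lv[2L])
      fit <- suppressWarnings(
        stats::glm(yb[obs] ~ ., data = df[obs, setdiff(names(df), target),
                                          drop = FALSE],
                   family = stats::binomial()))
      V <- suppressWarnings(stats::vcov(fit))
      if (anyNA(stats::coef(fit)) || anyNA(V))
        return(fallback("non-estimable logistic model"))
      beta <- MASS::mvrnorm(1L, stats::coef(fit), V)
      Xm <- stats::model.matrix(~ ., df[mis, setdiff(names(df), target),
                                        drop = FALSE])
      p <- stats::plogis(drop(Xm[, names(beta), drop = FALSE] %*% beta))
      draw <- stats::rbinom(sum(mis), 1L, p)
      lv[draw + 1L]
    } else if (family == "multinomial") {
      y <- factor(df[[target]][obs])
      fit <- nnet::multinom(y ~ ., data = df[obs, setdiff(names(df), target),
                                             drop = FALSE],
                            trace = FALSE, maxit = 200)
      p <- stats::predict(fit, newdata = df[mis, , drop = FALSE],
                          type = "probs")
      if (is.null(dim(p))) p <- rbind(p)
      lv <- colnames(p)
      apply(p, 1L, function(pr) sample(lv, 1L, prob = pr))
    } else {   # pmm
      y <- df[[target]]
      fit <- stats::lm(y[obs] ~ ., data = df[obs, setdiff(names(df), target),
                                             drop = FALSE])
      V <- stats::vcov(fit)
      if (anyNA(stats::coef(fit))) return(fallback("collinear PMM model"))
      beta_star <- MASS::mvrnorm(1L, stats::coef(fit), V)
      Xo <- stats::model.matrix(~ ., df[obs, setdiff(names(df), target),
                                        drop = FALSE])
      Xm <- stats::model.matrix(~ ., df[mis, setdiff(names(df), target),
                                        drop = FALSE])
      yhat_obs <- drop(Xo %*% stats::coef(fit))
      yhat_mis <- drop(Xm %*% beta_star)
      yobs <- y[obs]
      vapply(yhat_mis, function(v) {
        d <- abs(yhat_obs - v)
        k <- min(donors, length(d))
        donors_i <- order(d)[seq_len(k)]
        yobs[sample(donors_i, 1L)]
      }, numeric(1))
    }
  }, error = function(e) fallback(conditionMessage(e)))
}

#' Multivariate imputation by chained equations
#'
#' Imputes missing explanatory-variable cells by iterative conditional
#' modelling: after initializing each missing cell with a random draw from
#' the observed marginal, variables are visited in order of increasing
#' missingness each cycle, and each is re-imputed from a conditional model
#' (logistic, multinomial or predictive mean matching) regressing it on all
#' other explanatory variables plus age band and country.  Logistic and PMM
#' steps draw model coefficients from their approximate normal posterior;
#' PMM then samples from the `donors` observed cases with the nearest
#' predicted values.  A conditional model that cannot be fitted falls back
#' to a marginal draw for that cycle, and the event is logged in the
#' `"impute_log"` attribute.  Observed cells are never altered; outcomes and
#' income must be complete.  Deterministic given the schema seed.
#'
#' @param data microdata with missingness confined to explanatory variables.
#' @param schema an [imputation_schema()].
#' @return list of `m` completed datasets, with attribute `impute_log`.
#' @export
impute_chained <- function(data, schema = imputation_schema()) {
  stopifnot(inherits(schema, "imputation_schema"))
  for (v in c("adl", "iadl", "mobility", "income_pc")) {
    if (v %in% names(data) && v %in% schema$vars)
      stop("impute_chained: outcomes and income are not imputed")
  }
  vars <- intersect(schema$vars, names(data))
  mis_frac <- vapply(vars, function(v) mean(is.na(data[[v]])), numeric(1))
  if (any(mis_frac >= 1))
    stop("impute_chained: variable(s) 100% missing: ",
         paste(vars[mis_frac >= 1], collapse = ", "))
  visit <- vars[order(mis_frac)]                 # ties keep column order
  active <- visit[mis_frac[match(visit, vars)] > 0]
  if (!length(active)) {
    out <- replicate(schema$m, data, simplify = FALSE)
    attr(out, "impute_log") <- character(0)
    return(out)
  }
  families <- vapply(active, function(v) {
    if (!is.null(schema$families) && v %in% names(schema$families))
      schema$families[[v]] else infer_family(data[[v]])
  }, character(1))

  set.seed(schema$seed)
  log_env <- new.env()
  log_env$log <- character(0)
  # predictor frame: all schema vars + age band + country dummies
  pred_cols <- unique(c(vars, "age_band", "country_code"))
  completed <- vector("list", schema$m)
  for (im in seq_len(schema$m)) {
    d <- data
    for (v in active) {                          # marginal initialization
      mis <- is.na(d[[v]])
      d[[v]][mis] <- sample(d[[v]][!mis], sum(mis), replace = TRUE)
    }
    for (cycle in seq_len(schema$cycles)) {
      for (v in active) {
        mis <- is.na(data[[v]])
        if (!any(mis)) next
        df <- d[, pred_cols, drop = FALSE]
        df[] <- lapply(df, function(x) if (is.character(x)) factor(x) else x)
        df[[v]] <- d[[v]]
        if (is.character(data[[v]])) df[[v]] <- as.character(d[[v]])
        d[[v]][mis] <- impute_one(v, df, mis, families[[v]],
                                  schema$donors, log_env)
      }
    }
    completed[[im]] <- d
  }
  attr(completed, "impute_log") <- log_env$log
  completed
}
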
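#' Concentration indices for income-related health inequality
#'
#' Computes the standard concentration index \eqn{C = 2\,cov_w(h, R)/\mu} or
#' the Erreygers generalized concentration index
#' \eqn{E = 4\mu C/(b-a) = 8\,cov_w(h, R)/(b-a)} of a health variable `h`
#' over the weighted fractional income-rank distribution `R`.  The weighted
#' covariance uses weights normalized to sum to one.
#'
#' For bounded (in particular binary) health variables the standard index
#' violates the mirror condition: inequality measured in attainments need not
#' equal minus inequality measured in shortfalls.  The Erreygers correction
#' restores it, so that \eqn{E(h) = -E(1-h)} exactly, and keeps the index in
#' \eqn{[-1, 1]} for binary `h`.  Zero indicates no income-related
#' inequality; a negative value indicates a pro-poor concentration of the
#' outcome (the outcome — here, disability — is more prevalent among the
#' poor), a positive value a pro-rich concentration.
#'
#' The standard error is the survey-weighted standard deviation of the
#' per-observation recentred influence function (see [rif_erreygers()],
#' [rif_standard()]) divided by \eqn{\sqrt{n}}; the 95% interval is Wald.
#'
#' @param h numeric outcome vector; binary 0/1 for the Erreygers default
#'   bounds.  Missing values are not allowed (drop them upstream).
#' @param y incomes defining the rank variable.
#' @param w strictly positive weights (default equal).
#' @param type `"erreygers"` (default) or `"standard"`.
#' @param bounds length-2 vector `(a, b)` with `a < b`, the attainable range
#'   of `h`; used by the Erreygers index only.  Default `c(0, 1)`.
#' @return an object of class `index_estimate`: a list with `index_type`,
#'   `value`, `se`, `ci95`, `n`, `mu` (weighted mean of `h`), `bounds` and
#'   the `rif` vector (input order).
#' @examples
#' ci <- concentration_index(c(1, 1, 0, 0), y = 1:4)
#' ci$value   # -1: the outcome is entirely concentrated among the poorest
#' @export
concentration_index <- function(h, y, w = NULL,
                                type = c("erreygers", "standard"),
                                bounds = c(0, 1)) {
  type <- match.arg(type)
  n <- length(h)
  if (n == 0L) stop("concentration_index: empty input")
  if (length(y) != n) stop("concentration_index: 'h' and 'y' lengths differ")
  if (is.null(w)) w <- rep(1, n)
  if (length(w) == 1L) w <- rep(w, n)
  if (anyNA(h)) stop("concentration_index: missing outcomes; drop them upstream")
  wt <- w / sum(w)
  mu <- sum(wt * h)
  R <- fractional_rank(y, w)
  covw <- sum(wt * h * R) - mu * 0.5         # weighted mean of R is 1/2
  if (type == "standard") {
    if (mu <= 0) stop("concentration_index: standard index undefined for mean(h) = 0")
    value <- 2 * covw / mu
    rif <- rif_standard(h, y, w)
  } else {
    a <- bounds[1L]; b <- bounds[2L]
    if (!(a < b)) stop("concentration_index: bounds must satisfy a < b")
    if (any(h < a | h > b)) stop("concentration_index: outcome outside bounds")
    value <- 8 * covw / (b - a)
    rif <- rif_erreygers(h, y, w, bounds = bounds)
  }
  se <- sqrt(sum(wt * (rif - value)^2)) / sqrt(n)
  out <- list(index_type = type, value = value, se = se,
              ci95 = c(value - 1.959964 * se, value + 1.959964 * se),
              n = n, mu = mu,
              bounds = if (type == "erreygers") bounds else NULL,
              rif = rif)
  class(out) <- "index_estimate"
  out
}

#' @export
print.index_estimate <- function(x, ...) {
  lab <- if (x$index_type == "erreygers") "Erreygers concentration index"
         else "Standard concentration index"
  cat(sprintf("%s: %s (SE %s, 95%% CI %s to %s), n = %d\n",
              lab, format_index(x$value), format_index(x$se),
              format_index(x$ci95[1]), format_index(x$ci95[2]), x$n))
  invisible(x)
}

#' Per-country concentration indices
#'
#' Applies [concentration_index()] within each country (ranks computed
#' within country, matching the within-country income-quintile logic) for
#' one disability domain, dropping rows with a missing outcome listwise.
#'
#' @param data survey microdata (see [generate_microdata()] for the schema).
#' @param domain one of `"adl"`, `"iadl"`, `"mobility"`.
#' @param weighted use sampling weights (default) or equal weights.
#' @param type,bounds passed to [concentration_index()].
#' @return data frame with one row per country: `country_code`, `domain`,
#'   `n`, `index`, `se`, `ci_low`, `ci_high`.  Countries with no nonmissing
#'   outcome are omitted.
#' @export
country_indices <- function(data, domain = c("adl", "iadl", "mobility"),
                            weighted = TRUE,
                            type = c("erreygers", "standard"),
                            bounds = c(0, 1)) {
  domain <- match.arg(domain)
  type <- match.arg(type)
  keep <- !is.na(data[[domain]])
  d <- data[keep, , drop = FALSE]
  rows <- lapply(split(d, d$country_code, drop = TRUE), function(dc) {
    est <- concentration_index(dc[[domain]], dc$income_pc,
                               w = if (weighted) dc$sample_weight else NULL,
                               type = type, bounds = bounds)
    data.frame(country_code = dc$country_code[1L], domain = domain,
               n = est$n, index = est$value, se = est$se,
               ci_low = est$ci95[1L], ci_high = est$ci95[2L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Overall (multi-country) concentration index
#'
#' Pools the per-person recentred influence functions across countries.
#' With `ranks = "within"` (default) the index and RIF of each country are
#' computed against the country's own income ranks, and the overall value is
#' the survey-weighted mean of the pooled RIF vector — i.e. the weighted
#' average of the country indices.  With `ranks = "pooled"` a single global
#' ranking of per-capita income is used.
#'
#' @inheritParams country_indices
#' @param ranks `"within"` or `"pooled"`.
#' @return an `index_estimate` (the `rif` element is aligned to the
#'   nonmissing-outcome rows of `data`, in input order).
#' @export
overall_index <- function(data, domain = c("adl", "iadl", "mobility"),
                          weighted = TRUE, ranks = c("within", "pooled"),
                          type = c("erreygers", "standard"),
                          bounds = c(0, 1)) {
  domain <- match.arg(domain)
  ranks <- match.arg(ranks)
  type <- match.arg(type)
  keep <- !is.na(data[[domain]])
  d <- data[keep, , drop = FALSE]
  w <- if (weighted) d$sample_weight else rep(1, nrow(d))
  if (ranks == "pooled") {
    return(concentration_index(d[[domain]], d$income_pc, w,
                               type = type, bounds = bounds))
  }
  rif <- numeric(nrow(d))
  for (cc in unique(d$country_code)) {
    i <- d$country_code == cc
    est <- concentration_index(d[[domain]][i], d$income_pc[i], w[i],
                               type = type, bounds = bounds)
    rif[i] <- est$rif
  }
  wt <- w / sum(w)
  value <- sum(wt * rif)
  se <- sqrt(sum(wt * (rif - value)^2)) / sqrt(nrow(d))
  out <- list(index_type = type, value = value, se = se,
              ci95 = c(value - 1.959964 * se, value + 1.959964 * se),
              n = nrow(d), mu = sum(wt * d[[domain]]),
              bounds = if (type == "erreygers") bounds else NULL,
              rif = rif)
  class(out) <- "index_estimate"
  out
}
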
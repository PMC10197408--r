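#' Post-stratify sampling weights to a reference age composition
#'
#' Adjusts sampling weights within each country by a single multiplicative
#' factor per age band so that the weighted age-band shares equal the
#' reference population shares exactly, while preserving each country's total
#' weight.  This is single-margin post-stratification (no raking), the
#' standard adjustment for comparing prevalences across countries with
#' different age compositions.
#'
#' @param data survey microdata with `country_code`, `age_band`,
#'   `sample_weight`.
#' @param ref reference age structure: data frame with `age_band`, `share`
#'   (nonnegative, summing to 1); see [reference_age_structure()].
#' @return numeric vector of adjusted weights aligned to the rows of `data`.
#'   Idempotent: post-stratifying already-adjusted weights changes nothing.
#' @export
poststratify_weights <- function(data, ref) {
  stopifnot(all(c("age_band", "share") %in% names(ref)),
            all(c("country_code", "age_band", "sample_weight") %in% names(data)))
  if (any(ref$share < 0)) stop("poststratify_weights: negative reference share")
  if (abs(sum(ref$share) - 1) > 1e-9)
    stop("poststratify_weights: reference shares must sum to 1")
  unknown <- setdiff(unique(data$age_band), ref$age_band)
  if (length(unknown))
    stop("poststratify_weights: age band(s) absent from reference: ",
         paste(unknown, collapse = ", "))
  share <- stats::setNames(ref$share, ref$age_band)
  w_out <- numeric(nrow(data))
  for (cc in unique(data$country_code)) {
    i <- which(data$country_code == cc)
    w <- data$sample_weight[i]
    if (any(w <= 0)) stop("poststratify_weights: nonpositive weight in ", cc)
    band_w <- tapply(w, data$age_band[i], sum)
    missing_band <- setdiff(ref$age_band[ref$share > 0], names(band_w))
    if (length(missing_band))
      stop("poststratify_weights: no sampled weight in country ", cc,
           " for band(s) with positive reference share: ",
           paste(missing_band, collapse = ", "))
    W <- sum(w)
    factor <- share[names(band_w)] * W / band_w
    w_out[i] <- w * factor[match(data$age_band[i], names(band_w))]
  }
  unname(w_out)
}

#' Design-based weighted prevalence with a 95% confidence interval
#'
#' Estimates the prevalence of a binary outcome as the weighted mean
#' \eqn{\sum w_i h_i / \sum w_i} (in percent).  The variance is obtained by
#' Taylor linearization of the ratio estimator with clusters as primary
#' sampling units within strata (with-replacement approximation); when no
#' design identifiers are supplied, or when some stratum holds a single
#' cluster, the estimator falls back to the weighted simple-random-sampling
#' variance (with a warning in the single-cluster case).  The 95% interval
#' is Wald on the logit scale, back-transformed and truncated to
#' \[0, 100\]; degenerate at an all-0 or all-1 sample.
#'
#' @param h binary 0/1 outcome vector, no missing values (drop missing
#'   outcome rows upstream).
#' @param w strictly positive weights.
#' @param stratum,cluster optional design identifiers (same length as `h`).
#' @param label optional group label carried into the result.
#' @return one-row data frame: `group`, `n`, `prevalence`, `ci_low`,
#'   `ci_high` (percent).
#' @export
weighted_prevalence <- function(h, w = NULL, stratum = NULL, cluster = NULL,
                                label = "overall") {
  n <- length(h)
  if (n == 0L) stop("weighted_prevalence: empty input")
  if (anyNA(h)) stop("weighted_prevalence: missing outcomes; drop them upstream")
  if (!all(h %in% c(0, 1))) stop("weighted_prevalence: outcome must be 0/1")
  if (is.null(w)) w <- rep(1, n)
  if (any(w <= 0)) stop("weighted_prevalence: weights must be positive")
  W <- sum(w)
  p <- sum(w * h) / W

  srs_var <- function() {
    if (n < 2L) return(0)
    sum((w * (h - p))^2) / W^2 * n / (n - 1)
  }
  if (is.null(stratum) || is.null(cluster)) {
    v <- srs_var()
  } else {
    z <- w * (h - p) / W                     # linearized contributions
    strata <- unique(stratum)
    v <- 0
    fallback <- FALSE
    for (s in strata) {
      i <- stratum == s
      tc <- tapply(z[i], cluster[i], sum)    # cluster totals
      nh <- length(tc)
      if (nh < 2L) { fallback <- TRUE; break }
      v <- v + nh / (nh - 1) * sum((tc - mean(tc))^2)
    }
    if (fallback) {
      warning("weighted_prevalence: single-cluster stratum; ",
              "falling back to SRS variance")
      v <- srs_var()
    }
  }
  se <- sqrt(v)
  if (p <= 0 || p >= 1 || se == 0) {
    ci <- c(p, p)
  } else {
    l <- stats::qlogis(p)
    se_l <- se / (p * (1 - p))
    ci <- stats::plogis(l + c(-1, 1) * 1.959964 * se_l)
  }
  data.frame(group = label, n = n,
             prevalence = 100 * p,
             ci_low = max(0, 100 * ci[1L]),
             ci_high = min(100, 100 * ci[2L]),
             stringsAsFactors = FALSE)
}

# group assignment from the weighted empirical CDF with right-closed
# intervals: cut point q_j = min{ y : F(y) >= j/k }; group = 1 + #{q_j < y}.
weighted_quantile_groups <- function(y, w, k) {
  o <- order(y)
  ys <- y[o]; ws <- w[o]
  uy <- unique(ys)
  Fu <- cumsum(as.vector(rowsum(ws, match(ys, uy)))) / sum(ws)
  cuts <- vapply(seq_len(k - 1L) / k,
                 function(q) uy[which(Fu >= q - 1e-12)[1L]], numeric(1))
  vapply(y, function(v) 1L + sum(cuts < v), integer(1))
}

#' Within-country weighted income quintiles
#'
#' Assigns each person to an income quintile (1 = poorest, 5 = richest)
#' within their country, using weighted quintile cut points from the
#' weighted empirical CDF with right-closed intervals: a person falls in the
#' lowest quintile whose upper cut point is at least their income.  Exact
#' income ties (hence all members of one household) always share a quintile;
#' consequently a heavy boundary observation can displace the 20% weighted
#' shares by up to its own weight.
#'
#' @param data microdata with `country_code`, `income_pc`, `sample_weight`.
#' @return integer vector of quintiles aligned to the rows of `data`.
#' @export
assign_income_quintiles <- function(data) {
  if (anyNA(data$income_pc)) stop("assign_income_quintiles: missing income")
  q <- integer(nrow(data))
  for (cc in unique(data$country_code)) {
    i <- which(data$country_code == cc)
    if (length(unique(data$income_pc[i])) < 5L)
      stop("assign_income_quintiles: fewer than 5 distinct incomes in ", cc)
    q[i] <- weighted_quantile_groups(data$income_pc[i],
                                     data$sample_weight[i], 5L)
  }
  q
}

#' Country quartiles of a macro indicator
#'
#' Assigns each country to a quartile (1 = lowest, 4 = highest) of one
#' macro indicator, unweighted across countries; tied countries share the
#' lower quartile.
#'
#' @param macro country-level table (see [generate_macro()]).
#' @param variable name of the indicator column.
#' @return named integer vector, country code -> quartile.
#' @export
assign_country_quartiles <- function(macro, variable) {
  x <- macro[[variable]]
  if (is.null(x)) stop("assign_country_quartiles: unknown variable ", variable)
  ok <- !is.na(x)
  if (sum(ok) < 4L)
    stop("assign_country_quartiles: need >= 4 countries with nonmissing '",
         variable, "'")
  q <- rep(NA_integer_, length(x))
  q[ok] <- weighted_quantile_groups(x[ok], rep(1, sum(ok)), 4L)
  stats::setNames(q, macro$country_code)
}

#' Quintile percentage difference in prevalence
#'
#' The relative prevalence gap between the poorest and richest quintile:
#' ((quintile 1 - quintile 5) / quintile 1) x 100.
#'
#' @param p_q1 prevalence (percent) in the poorest quintile; must be > 0.
#' @param p_q5 prevalence (percent) in the richest quintile.
#' @return percentage difference.
#' @examples
#' percentage_difference(20, 10)  # 50
#' @export
percentage_difference <- function(p_q1, p_q5) {
  if (any(p_q1 <= 0))
    stop("percentage_difference: undefined for quintile-1 prevalence of 0")
  (p_q1 - p_q5) / p_q1 * 100
}

#' Prevalence table by country (and optionally by income quintile)
#'
#' Post-stratifies weights to the reference age structure, drops rows with a
#' missing outcome listwise per domain, and tabulates design-based weighted
#' prevalences by country, optionally within income quintiles.
#'
#' @param data survey microdata.
#' @param ref reference age structure.
#' @param domains subset of `c("adl", "iadl", "mobility")`.
#' @param by_quintile also split by within-country income quintile.
#' @return data frame: `domain`, `country_code`, (`quintile`,) `group`, `n`,
#'   `prevalence`, `ci_low`, `ci_high`.
#' @export
prevalence_table <- function(data, ref,
                             domains = c("adl", "iadl", "mobility"),
                             by_quintile = FALSE) {
  w_ps <- poststratify_weights(data, ref)
  quint <- if (by_quintile) assign_income_quintiles(data) else NULL
  rows <- list()
  for (dom in domains) {
    ok <- !is.na(data[[dom]])
    for (cc in unique(data$country_code)) {
      i <- which(ok & data$country_code == cc)
      if (!length(i)) next
      if (by_quintile) {
        for (qq in sort(unique(quint[i]))) {
          j <- i[quint[i] == qq]
          est <- weighted_prevalence(data[[dom]][j], w_ps[j],
                                     data$stratum_id[j], data$cluster_id[j],
                                     label = sprintf("%s Q%d", cc, qq))
          rows[[length(rows) + 1L]] <-
            cbind(domain = dom, country_code = cc, quintile = qq, est)
        }
      } else {
        est <- weighted_prevalence(data[[dom]][i], w_ps[i],
                                   data$stratum_id[i], data$cluster_id[i],
                                   label = cc)
        rows[[length(rows) + 1L]] <-
          cbind(domain = dom, country_code = cc, est)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
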
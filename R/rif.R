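#' Recentred influence function of the Erreygers index
#'
#' Returns the per-observation recentred influence function (RIF) of the
#' Erreygers generalized concentration index.  With probability-normalized
#' weights, fractional ranks \eqn{R_i}, \eqn{A = \sum_i w_i h_i R_i / W} and
#' the upper-tail outcome share
#' \deqn{s_i = \sum_j w_j h_j (1\{y_j > y_i\} + \tfrac12 1\{y_j = y_i\})/W,}
#' the RIF is
#' \deqn{RIF_i = 4 h_i (2 R_i - 1) + 8 (s_i - A).}
#'
#' Under the block-midpoint tie convention of [fractional_rank()] the
#' weighted mean of the RIF equals the index exactly, so a regression of the
#' RIF on covariates decomposes the index, and the weighted RIF standard
#' deviation over \eqn{\sqrt n} is a linearization-based standard error.
#' First-order validity: multiplying one weight \eqn{w_i} by \eqn{1+\epsilon}
#' changes the index by \eqn{\epsilon\, w_i (RIF_i - E)/W + O(\epsilon^2)}.
#'
#' @inheritParams concentration_index
#' @return numeric RIF vector aligned to the input order.
#' @export
rif_erreygers <- function(h, y, w = NULL, bounds = c(0, 1)) {
  n <- length(h)
  if (n == 0L) stop("rif_erreygers: empty input")
  if (is.null(w)) w <- rep(1, n)
  if (length(w) == 1L) w <- rep(w, n)
  a <- bounds[1L]; b <- bounds[2L]
  if (!(a < b)) stop("rif_erreygers: bounds must satisfy a < b")
  if (anyNA(h) || any(h < a | h > b)) stop("rif_erreygers: outcome outside bounds")
  W <- sum(w)
  R <- fractional_rank(y, w)
  A <- sum(w * h * R) / W
  s <- upper_tail_share(h, y, w)
  scale <- 1 / (b - a)
  scale * (4 * h * (2 * R - 1) + 8 * (s - A))
}

#' Recentred influence function of the standard concentration index
#'
#' RIF of \eqn{C = 2 cov_w(h, R)/\mu}:
#' \deqn{RIF_i = C + \frac{2}{\mu}(h_i R_i + s_i - 2A)
#'               - \frac{(C + 1)(h_i - \mu)}{\mu},}
#' with \eqn{A} and \eqn{s_i} as in [rif_erreygers()].  Its weighted mean
#' equals \eqn{C} exactly, and
#' \eqn{RIF^E_i = 4\mu\,RIF^C_i + 4C(h_i - \mu)} links the two variants.
#'
#' @inheritParams concentration_index
#' @return numeric RIF vector aligned to the input order.
#' @export
rif_standard <- function(h, y, w = NULL) {
  n <- length(h)
  if (n == 0L) stop("rif_standard: empty input")
  if (is.null(w)) w <- rep(1, n)
  if (length(w) == 1L) w <- rep(w, n)
  if (anyNA(h)) stop("rif_standard: missing outcomes")
  W <- sum(w)
  mu <- sum(w * h) / W
  if (mu <= 0) stop("rif_standard: undefined for mean(h) = 0")
  R <- fractional_rank(y, w)
  A <- sum(w * h * R) / W
  s <- upper_tail_share(h, y, w)
  C <- 2 * (A - mu / 2) / mu
  C + (2 / mu) * (h * R + s - 2 * A) - (C + 1) * (h - mu) / mu
}

# s_i = sum_j w_j h_j (1{y_j > y_i} + 1/2 * 1{y_j = y_i}) / W,
# computed in O(n log n) via reverse cumulative block sums of w*h.
upper_tail_share <- function(h, y, w) {
  W <- sum(w)
  o <- order(y)
  ys <- y[o]
  wh <- (w * h)[o]
  blk <- cumsum(!duplicated(ys))
  bwh <- as.vector(rowsum(wh, blk))
  tot <- sum(bwh)
  s_blk <- (tot - cumsum(bwh) + bwh / 2) / W   # strictly above + half own block
  s <- numeric(length(y))
  s[o] <- s_blk[blk]
  s
}
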
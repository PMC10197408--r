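#' Weighted fractional income ranks
#'
#' Computes the weighted fractional (mid-point) rank of each observation in
#' the income distribution.  Observations are sorted by `y`; each block of
#' tied values receives the single rank
#' \deqn{R = (W_{<} + W_{=}/2) / W,}
#' where \eqn{W_{<}} is the total weight strictly below the block,
#' \eqn{W_{=}} the block's own weight and \eqn{W} the total weight.  Ranks
#' are returned in the input order.
#'
#' The block-midpoint convention makes the weighted mean of the ranks exactly
#' 1/2 and keeps the mirror and mean-RIF identities of the Erreygers index
#' exact in the presence of ties.
#'
#' @param y numeric vector of incomes (any sortable living-standards
#'   variable; only its ordering matters).
#' @param w strictly positive sampling weights, recycled to `length(y)` if
#'   scalar.  Default: equal weights.
#' @return numeric vector of ranks in (0, 1), aligned to `y`.
#' @examples
#' fractional_rank(c(1, 2, 3, 4))          # 0.125 0.375 0.625 0.875
#' fractional_rank(c(1, 1, 2), c(1, 1, 2)) # ties share a rank
#' @export
fractional_rank <- function(y, w = NULL) {
  n <- length(y)
  if (n == 0L) stop("fractional_rank: empty input")
  if (is.null(w)) w <- rep(1, n)
  if (length(w) == 1L) w <- rep(w, n)
  if (length(w) != n) stop("fractional_rank: 'y' and 'w' lengths differ")
  if (anyNA(y) || anyNA(w)) stop("fractional_rank: missing values not allowed")
  if (any(w <= 0)) stop("fractional_rank: weights must be strictly positive")
  W <- sum(w)
  o <- order(y)
  ys <- y[o]
  ws <- w[o]
  blk <- cumsum(!duplicated(ys))             # tie-block id, sorted order
  bw <- as.vector(rowsum(ws, blk))           # block weights
  r_blk <- (cumsum(bw) - bw / 2) / W         # W_below + W_block/2, scaled
  R <- numeric(n)
  R[o] <- r_blk[blk]
  R
}
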
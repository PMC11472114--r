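#' Rank-normalise a vector of per-area values
#'
#' Converts raw values to normalised mean ranks `R` in `(0, 1]`, the shared
#' primitive behind the vulnerability index, decile ranking and tercile
#' classification. Ties receive their mean rank; `R = mean_rank / N` where
#' `N` counts non-missing values, so the (untied) largest value maps to 1.
#'
#' @param values Numeric vector; `NA` values are excluded from ranking and
#'   propagate as `NA` in the result.
#' @param direction `+1` (default) if larger values mean more
#'   vulnerable/exposed, `-1` to reverse the ordering before ranking.
#' @return Numeric vector of normalised ranks, same length and order as
#'   `values`, with attribute `n_nonmissing`.
#' @examples
#' rank_normalise(c(0.2, 0.5, 0.9))      # 1/3, 2/3, 1
#' rank_normalise(c(0.5, 0.5))           # 0.75, 0.75 (mean rank 1.5 of 2)
#' @export
rank_normalise <- function(values, direction = 1L) {
  stopifnot(is.numeric(values))
  if (!direction %in% c(-1L, 1L)) {
    stop("`direction` must be +1 or -1", call. = FALSE)
  }
  ok <- !is.na(values)
  n <- sum(ok)
  if (n == 0L) stop("all values are missing; nothing to rank", call. = FALSE)
  r <- rep(NA_real_, length(values))
  r[ok] <- rank(direction * values[ok], ties.method = "average") / n
  structure(r, n_nonmissing = n)
}

#' Exponential transformation of normalised ranks to a 0-100 score
#'
#' The monotone map used by the English Indices of Multiple Deprivation to
#' spread the vulnerable tail of a rank distribution onto a 0-100 scale:
#' `score = -scale * log(1 - R * (1 - exp(-100/scale)))`. It is a bijection
#' from `(0, 1]` onto `(0, 100]` for every positive `scale`, with
#' `score(1) = 100` exactly.
#'
#' @param R Normalised ranks in `(0, 1]`; `NA` propagates.
#' @param scale Positive spread parameter; the conventional default is 23.
#'   Larger values make the transform nearly linear in `R`.
#' @return Scores in `(0, 100]`.
#' @examples
#' exponential_transform(1)            # exactly 100
#' exponential_transform(0.5)          # about 15.65
#' @export
exponential_transform <- function(R, scale = 23) {
  stopifnot(is.numeric(R), length(scale) == 1L, is.finite(scale))
  if (scale <= 0) stop("`scale` must be positive", call. = FALSE)
  ok <- !is.na(R)
  if (any(R[ok] <= 0 | R[ok] > 1)) {
    stop("normalised ranks must lie in (0, 1]", call. = FALSE)
  }
  # algebraically 1 - R*(1 - e); the regrouped form keeps the argument
  # positive in floating point even when exp(-100/scale) is tiny
  -scale * log((1 - R) + R * exp(-100 / scale))
}

# Shared rank-binning rule: bin = ceiling(k * mean_rank / N). mean ranks are
# multiples of 1/2, so k * rank / N sits at least 1/(2N) away from any integer
# it does not equal; the epsilon only absorbs floating-point representation
# error and cannot move a genuine non-integer across a bin edge.
rank_bin <- function(values, k) {
  R <- rank_normalise(values)
  bin <- rep(NA_integer_, length(values))
  ok <- !is.na(R)
  bin[ok] <- as.integer(ceiling(k * R[ok] - 1e-9))
  bin
}

#' Decile rank (1 = least, 10 = most exposed/vulnerable)
#'
#' Bins areas into deciles by `ceiling(10 * R)` of the normalised mean rank,
#' so tied values always share a decile and the result does not depend on
#' input order.
#'
#' @param values Numeric vector; `NA` excluded and propagated.
#' @return Integer deciles 1..10.
#' @examples
#' decile_rank(1:10)          # 1..10, one each
#' decile_rank(rep(2, 10))    # all 6: mean rank 5.5, R = 0.55
#' @export
decile_rank <- function(values) rank_bin(values, 10L)

#' Tercile classification (1 = lowest, 3 = highest)
#'
#' Bins areas into terciles by `ceiling(3 * R)` of the normalised mean rank;
#' the rank-based analogue of [decile_rank()] used for the 3x3 risk matrix.
#'
#' @param values Numeric vector; `NA` excluded and propagated.
#' @return Integer terciles 1..3.
#' @examples
#' tercile_classify(c(1, 2, 3))   # 1, 2, 3
#' @export
tercile_classify <- function(values) rank_bin(values, 3L)

# Weighted mean across the columns of `x` with weights renormalised over the
# non-missing entries of each row. Rows with no usable entry return NA.
weighted_mean_renorm <- function(x, weights) {
  stopifnot(is.matrix(x), length(weights) == ncol(x), all(weights >= 0))
  w <- matrix(weights, nrow = nrow(x), ncol = ncol(x), byrow = TRUE)
  w[is.na(x)] <- 0
  tot <- rowSums(w)
  num <- rowSums(x * w, na.rm = TRUE)
  ifelse(tot > 0, num / tot, NA_real_)
}
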
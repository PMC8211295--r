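#' Normal-score (rank order) transformation
#'
#' Maps observed values onto the standardized rank space: average ranks for
#' ties, plotting position (rank - 0.5)/n, then the standard normal quantile
#' function. Most soil and microbial variables are far from Gaussian; kriging
#' is carried out on these normal scores and predictions are mapped back with
#' [back_transform()].
#'
#' @param values Numeric vector, n >= 3, all finite.
#' @return A list of class `rank_map` with elements `scores` (the transformed
#'   vector, same order as input), `values_sorted` and `scores_sorted` (the
#'   monotone lookup table used by the inverse map), and `n`.
#' @export
rank_transform <- function(values) {
  if (!is.numeric(values) || length(values) < 3L) {
    stop("need at least 3 numeric values")
  }
  if (any(!is.finite(values))) stop("values must be finite")
  if (diff(range(values)) == 0) {
    stop("all values identical: no signal to rank-transform")
  }
  n <- length(values)
  r <- rank(values, ties.method = "average")
  scores <- stats::qnorm((r - 0.5) / n)
  ord <- order(values)
  vs <- values[ord]
  ss <- scores[ord]
  keep <- !duplicated(vs)
  structure(list(scores = scores,
                 values_sorted = vs[keep],
                 scores_sorted = ss[keep],
                 n = n),
            class = "rank_map")
}

#' Back-transform normal scores to the original scale
#'
#' Inverts the normal-score map by monotone linear interpolation between the
#' observed (score, value) quantile pairs; predictions beyond the observed
#' score range clamp to the observed minimum/maximum (the count of clamped
#' points is attached as an attribute).
#'
#' @param scores Numeric vector of rank-space values (e.g. kriging estimates).
#' @param rankmap A `rank_map` from [rank_transform()].
#' @return Numeric vector on the original scale, with attribute `n_clamped`.
#' @export
back_transform <- function(scores, rankmap) {
  if (!inherits(rankmap, "rank_map")) stop("`rankmap` must be a rank_map")
  lo <- min(rankmap$scores_sorted)
  hi <- max(rankmap$scores_sorted)
  n_clamped <- sum(scores < lo | scores > hi, na.rm = TRUE)
  out <- stats::approx(rankmap$scores_sorted, rankmap$values_sorted,
                       xout = pmin(pmax(scores, lo), hi),
                       method = "linear", ties = "ordered")$y
  attr(out, "n_clamped") <- n_clamped
  out
}
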
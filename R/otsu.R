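#' Otsu threshold by exact between-class-variance search
#'
#' Finds the threshold maximizing the between-class variance of the values
#' split into `{v < t}` and `{v >= t}`.  Candidate thresholds are the 256 bin
#' midpoints of a uniform binning of `[lo, hi]`; the variance at each
#' candidate is computed from the raw values (exact search, not histogram
#' moments).  Ties are broken toward the lowest candidate.
#'
#' Used both for tissue detection on HSV channels and for binarizing score
#' maps, where it is applied to the scores of the originally-positive patches
#' only (see [refine()]).
#'
#' @param values numeric vector with at least two distinct values.
#' @param range numeric length-2 binning range, default `c(0, 1)`.
#' @param n_bins number of bins, default 256.
#' @return the threshold, a bin midpoint in `(lo, hi)`.
#' @export
otsu_threshold <- function(values, range = c(0, 1), n_bins = 256L) {
  values <- values[is.finite(values)]
  if (length(values) < 2 || max(values) == min(values)) {
    stop_degenerate("Otsu threshold undefined: fewer than two distinct values")
  }
  lo <- range[1]; hi <- range[2]
  stopifnot(hi > lo, all(values >= lo), all(values <= hi))
  width <- (hi - lo) / n_bins
  cand <- lo + (seq_len(n_bins) - 0.5) * width

  n <- length(values)
  v <- sort(values)
  csum <- cumsum(v)
  total <- csum[n]
  # n0[k]: how many values fall strictly below candidate k
  n0 <- findInterval(cand, v, left.open = TRUE)
  n1 <- n - n0
  ok <- n0 > 0 & n1 > 0
  if (!any(ok)) stop_degenerate("Otsu threshold undefined: no valid split")
  s0 <- ifelse(n0 > 0, csum[pmax(n0, 1)], 0)
  s0[n0 == 0] <- 0
  mu0 <- s0 / pmax(n0, 1)
  mu1 <- (total - s0) / pmax(n1, 1)
  bcv <- ifelse(ok, (n0 / n) * (n1 / n) * (mu0 - mu1)^2, -Inf)
  cand[which.max(bcv)]
}
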
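#' Nonparametric percentile reference interval in a truncation window
#'
#' The plain CLSI-style nonparametric estimator: empirical quantiles of the
#' values inside the window at `probs`, using rank `rank = p(n+1)` with linear
#' interpolation between order statistics and the rank clamped to `[1, n]`
#' (identical to `stats::quantile(type = 6)`). At least 120 in-window
#' values are required — the conventional minimum for nonparametric
#' reference limits.
#'
#' @param values raw-scale values (the full sample; the window selects).
#' @param window a `truncation_window`, or `NULL` for the full range.
#' @param probs the two reference-limit probabilities.
#' @param min_n minimum in-window sample size.
#' @return Named numeric `c(lower, upper)`.
#' @export
estimate_percentile_ri <- function(values, window = NULL,
                                   probs = c(0.025, 0.975), min_n = 120) {
  v <- values[is.finite(values)]
  if (!is.null(window)) v <- v[v >= window$lower & v <= window$upper]
  if (length(v) < min_n) {
    stop("estimate_percentile_ri: only ", length(v),
         " values in the window; need at least ", min_n, call. = FALSE)
  }
  q <- quantile(v, probs = probs, type = 6, names = FALSE)
  setNames(q, c("lower", "upper")[seq_along(probs)])
}

#' Responsibility-weighted rank percentile
#'
#' Weighted analogue of the `rank = p(n+1)` estimator: with sorted values
#' and cumulative weights `c_i`, the quantile sits at weighted rank
#' `rank = p(W+1)` (`W` the total weight), linearly interpolated in cumulative
#' weight between adjacent order statistics and clamped to the data range.
#' With unit weights this reduces exactly to the plain estimator.
#'
#' @param values numeric values.
#' @param weights non-negative weights (posterior responsibilities in the
#'   pipeline).
#' @param probs probabilities.
#' @return Quantile estimates, one per prob.
#' @export
weighted_rank_quantile <- function(values, weights, probs) {
  stopifnot(length(values) == length(weights), all(weights >= 0))
  ok <- is.finite(values) & is.finite(weights)
  .weighted_rank_quantile(values[ok], weights[ok], probs)
}

#' Percentile-bootstrap confidence intervals for reference limits
#'
#' Resamples the in-window values (with their weights, when given) with
#' replacement `n_boot` times, recomputes the rank-percentile estimates,
#' and returns the central `level` span (percentile bootstrap: the
#' `(1-level)/2` and `(1+level)/2` quantiles of the bootstrap
#' distribution) for each reference limit. All randomness flows through
#' R's RNG, so results are reproducible for a fixed seed.
#'
#' @param values_in_window raw-scale values inside the truncation window.
#' @param weights optional responsibilities; `NULL` means unweighted.
#' @param probs the reference-limit probabilities.
#' @param level confidence level of the interval.
#' @param n_boot number of bootstrap resamples.
#' @param seed integer seed.
#' @param adjusted_probs probabilities actually evaluated on each resample
#'   (the pipeline passes healthy-mass-adjusted probs); defaults to
#'   `probs`.
#' @param min_n minimum sample size, as in [estimate_percentile_ri()].
#' @return A list with `lower_ci` and `upper_ci`, each `c(lo, hi)`.
#' @export
bootstrap_ci <- function(values_in_window, weights = NULL,
                         probs = c(0.025, 0.975), level = 0.90,
                         n_boot = 1000, seed = 1, adjusted_probs = probs,
                         min_n = 120) {
  v <- values_in_window[is.finite(values_in_window)]
  n <- length(v)
  if (n < min_n) {
    stop("bootstrap_ci: only ", n, " values; need at least ", min_n,
         call. = FALSE)
  }
  set.seed(seed)
  idx <- sample.int(n, n * n_boot, replace = TRUE)
  est <- if (is.null(weights)) {
    .boot_rank_quantiles(v, idx, n_boot, adjusted_probs)
  } else {
    stopifnot(length(weights) == length(values_in_window))
    .boot_weighted_quantiles(v, weights[is.finite(values_in_window)], idx,
                             n_boot, adjusted_probs)
  }
  a <- (1 - level) / 2
  cis <- apply(est, 2, quantile, probs = c(a, 1 - a), type = 6, names = FALSE)
  list(lower_ci = cis[, 1], upper_ci = cis[, 2])
}
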
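#' Harris-Boyd sex-partitioning decision
#'
#' Decides whether subgroup-specific reference intervals are warranted.
#' The test statistic is
#' `z = |mean1 - mean2| / sqrt(s1^2/n1 + s2^2/n2)`, compared against the
#' sample-size-scaled critical value `z* = 3 * sqrt(nbar / 120)` with
#' `nbar = (n1 + n2)/2`; partitioning is also required when the ratio of
#' the larger to the smaller SD reaches `sd_ratio_threshold`. The
#' criterion assumes near-Gaussian groups, so in the pipeline it is
#' applied on the transformed scale produced by [select_transform()]
#' (see [run_study()]); pass raw values to use the raw scale.
#'
#' @param group1,group2 numeric samples (each n >= 2, positive variance).
#' @param sd_ratio_threshold SD-ratio partitioning threshold.
#' @param z_scale multiplier in the critical value (3 is the conventional
#'   choice).
#' @return An object of class `partition_decision`: `z`, `z_star`,
#'   `sd_ratio`, `n1`, `n2`, `means`, `sds`, `partition_required`,
#'   `rationale`.
#' @export
#' @examples
#' harris_boyd(rnorm(120), rnorm(120, 0.5)) # borderline at n = 120
harris_boyd <- function(group1, group2, sd_ratio_threshold = 1.5,
                        z_scale = 3) {
  g1 <- group1[is.finite(group1)]
  g2 <- group2[is.finite(group2)]
  n1 <- length(g1)
  n2 <- length(g2)
  if (n1 < 2 || n2 < 2) {
    stop("harris_boyd: both groups need at least 2 values", call. = FALSE)
  }
  s1 <- sd(g1)
  s2 <- sd(g2)
  if (s1 == 0 || s2 == 0) {
    stop("harris_boyd: zero variance in a group", call. = FALSE)
  }
  m1 <- mean(g1)
  m2 <- mean(g2)
  z <- abs(m1 - m2) / sqrt(s1^2 / n1 + s2^2 / n2)
  z_star <- z_scale * sqrt(((n1 + n2) / 2) / 120)
  sd_ratio <- max(s1, s2) / min(s1, s2)
  required <- (z > z_star) || (sd_ratio >= sd_ratio_threshold)
  rationale <- if (!required) {
    sprintf("z = %.3f <= z* = %.3f and SD ratio %.3f < %.2f: common interval",
            z, z_star, sd_ratio, sd_ratio_threshold)
  } else if (z > z_star) {
    sprintf("z = %.3f > z* = %.3f: partition", z, z_star)
  } else {
    sprintf("SD ratio %.3f >= %.2f: partition", sd_ratio, sd_ratio_threshold)
  }
  structure(list(
    z = z, z_star = z_star, sd_ratio = sd_ratio, n1 = n1, n2 = n2,
    means = c(m1, m2), sds = c(s1, s2),
    partition_required = required, rationale = rationale
  ), class = "partition_decision")
}

#' @export
print.partition_decision <- function(x, ...) {
  cat("Harris-Boyd partition check:",
      if (x$partition_required) "PARTITION" else "common interval", "\n ",
      x$rationale, sprintf("(n1 = %d, n2 = %d)\n", x$n1, x$n2))
  invisible(x)
}

#' Mann-Whitney (Wilcoxon rank-sum) comparison of two groups
#'
#' Two-sided rank-sum test using the normal approximation with tie
#' correction (delegated to `stats::wilcox.test(exact = FALSE,
#' correct = FALSE)`). The returned `U` is the number of (group1, group2)
#' pairs won by group1.
#'
#' @param group1,group2 non-empty numeric samples.
#' @return A list with `U` and `p`.
#' @export
mann_whitney <- function(group1, group2) {
  g1 <- group1[is.finite(group1)]
  g2 <- group2[is.finite(group2)]
  if (length(g1) == 0 || length(g2) == 0) {
    stop("mann_whitney: both groups must be non-empty", call. = FALSE)
  }
  wt <- suppressWarnings(wilcox.test(g1, g2, exact = FALSE, correct = FALSE))
  p <- wt$p.value
  if (is.nan(p)) p <- 1 # zero-variance degenerate case
  list(U = unname(wt$statistic), p = min(max(p, .Machine$double.xmin), 1))
}
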
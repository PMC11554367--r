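#' Control parameters for the indirect RI pipeline
#'
#' One place for every tunable of [run_indirect_ri()]. Defaults:
#' medcouple-adjusted fences `3 * IQR * exp(+-{3,4} MC)` (gross-error
#' fences; see [detect_outliers()]); Box-Cox grid
#' `{-1,-0.5,0,0.5,1}` gated on |skew| <= 0.5 and |excess kurtosis| <= 1,
#' with lambda chosen by Jacobian-corrected mixture BIC;
#' Gaussian mixture with `k_max = 4`, EM tolerance 1e-8, 1000 iterations,
#' 5 restarts, BIC selection; responsibility threshold 0.1 with antimode
#' override; responsibility-weighted percentiles with healthy-mass
#' adjustment (`estimator = "weighted"`); 1000 bootstrap resamples at 90%
#' confidence; at least 120 in-window values.
#'
#' @param k_max maximum mixture components.
#' @param fence_const,exp_lower,exp_upper adjusted-boxplot fence constants
#'   (see [detect_outliers()]).
#' @param skew_gate,kurt_gate identity gates for [select_transform()].
#' @param resp_threshold posterior-responsibility window level.
#' @param lambda_rule Box-Cox lambda selection rule, see
#'   [select_transform()].
#' @param estimator `"weighted"` (responsibility-weighted, mass-adjusted)
#'   or `"plain"` (unweighted percentiles of the truncated sample).
#' @param probs reference-limit probabilities.
#' @param ci_level,n_boot bootstrap confidence level and resample count.
#' @param min_n minimum in-window sample size.
#' @param em_tol,em_max_iter,em_restarts EM controls.
#' @param check_monotone assert monotone EM log-likelihood each iteration.
#' @return A list of class `ri_control`.
#' @export
ri_control <- function(k_max = 4, fence_const = 3, exp_lower = 4,
                       exp_upper = 3, skew_gate = 0.5, kurt_gate = 1,
                       resp_threshold = 0.1,
                       lambda_rule = c("mixture_bic", "skewness"),
                       estimator = c("weighted", "plain"),
                       probs = c(0.025, 0.975), ci_level = 0.90,
                       n_boot = 1000, min_n = 120, em_tol = 1e-8,
                       em_max_iter = 1000, em_restarts = 5,
                       check_monotone = FALSE) {
  estimator <- match.arg(estimator)
  lambda_rule <- match.arg(lambda_rule)
  structure(list(
    k_max = k_max, fence_const = fence_const, exp_lower = exp_lower,
    exp_upper = exp_upper, skew_gate = skew_gate, kurt_gate = kurt_gate,
    resp_threshold = resp_threshold, lambda_rule = lambda_rule,
    estimator = estimator, probs = probs,
    ci_level = ci_level, n_boot = n_boot, min_n = min_n, em_tol = em_tol,
    em_max_iter = em_max_iter, em_restarts = em_restarts,
    check_monotone = check_monotone
  ), class = "ri_control")
}

#' Indirect reference-interval estimation from a mixed sample
#'
#' The full statistical core, composing:
#' \enumerate{
#'   \item [detect_outliers()] — medcouple-adjusted boxplot fences on the
#'     raw scale;
#'   \item [select_transform()] — identity or Box-Cox chosen by
#'     skewness/kurtosis analysis;
#'   \item [fit_mixture()] — Gaussian-mixture EM with BIC selection on the
#'     transformed scale;
#'   \item [find_modes_antimodes()] — KDE modes/antimodes;
#'   \item [choose_truncation()] — posterior-responsibility window with
#'     antimode override, isolating the presumed-healthy component;
#'   \item percentile estimation — by default the responsibility-weighted
#'     `rank = p(W+1)` rank percentile of the in-window values, with the
#'     target probabilities rescaled by the healthy-component mass the
#'     window cuts off (so the estimate targets the *healthy* 2.5th and
#'     97.5th percentiles, not those of the truncated mixture); with
#'     `estimator = "plain"`, the unweighted truncated percentiles;
#'   \item [bootstrap_ci()] — percentile-bootstrap confidence intervals.
#' }
#' With `k_max = 1` the window is the full data range, all weights are 1
#' and no mass adjustment occurs, so the result equals plain `rank = p(n+1)`
#' percentiles of the outlier-cleaned sample exactly.
#'
#' @param values raw-scale analyte values; n >= 500 recommended (a warning
#'   is issued below that).
#' @param control an [ri_control()].
#' @param seed integer seed (EM restarts and bootstrap).
#' @return An object of class `ri_estimate`: `lower`, `upper`, `lower_ci`,
#'   `upper_ci`, counts (`n_input`, `n_after_outliers`, `n_in_window`),
#'   `probs`, `transform`, `mixture`, `window`, `outliers`, `estimator`,
#'   `adjusted_probs`, `seed`.
#' @export
run_indirect_ri <- function(values, control = ri_control(), seed = 1) {
  # sorting makes every stage (and hence the estimate) exactly invariant
  # to the input order
  v <- sort(values[is.finite(values)])
  n_input <- length(v)
  if (n_input < 500) {
    warning("run_indirect_ri: n = ", n_input,
            " is below the recommended 500; estimates will be unstable",
            call. = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("run_indirect_ri [%s]: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  out <- stage("detect_outliers",
               detect_outliers(v, control$fence_const, control$exp_lower,
                               control$exp_upper))
  kept <- out$kept
  tr <- stage("select_transform",
              select_transform(kept, control$skew_gate, control$kurt_gate,
                               lambda_rule = control$lambda_rule,
                               k_max = control$k_max))
  kt <- apply_transform(kept, tr)
  mix <- stage("fit_mixture",
               fit_mixture(kt, k_max = control$k_max, seed = seed,
                           tol = control$em_tol,
                           max_iter = control$em_max_iter,
                           n_restarts = control$em_restarts,
                           check_monotone = control$check_monotone))
  modes <- stage("find_modes_antimodes", find_modes_antimodes(kt))
  win <- stage("choose_truncation",
               choose_truncation(mix, modes, tr, range(kept),
                                 resp_threshold = control$resp_threshold))
  inw <- kept >= win$lower & kept <= win$upper
  n_in_window <- sum(inw)
  if (n_in_window < control$min_n) {
    stop("run_indirect_ri [estimate_percentile_ri]: only ", n_in_window,
         " values in the truncation window; need at least ", control$min_n,
         call. = FALSE)
  }
  # healthy-mass adjustment: map the target healthy probabilities to
  # within-window probabilities using the fitted healthy component's mass
  mass_in <- 1 - win$mass_below - win$mass_above
  padj <- pmin(pmax((control$probs - win$mass_below) / mass_in, 0), 1)
  if (control$estimator == "weighted" && mix$k > 1) {
    wts <- responsibilities(mix, apply_transform(kept[inw], tr),
                            component = win$healthy_component)
    est <- stage("estimate_percentile_ri",
                 weighted_rank_quantile(kept[inw], wts, padj))
    cis <- stage("bootstrap_ci",
                 bootstrap_ci(kept[inw], weights = wts, probs = control$probs,
                              level = control$ci_level,
                              n_boot = control$n_boot, seed = seed,
                              adjusted_probs = padj, min_n = control$min_n))
  } else {
    # plain truncated percentiles at the unadjusted probabilities; with
    # k = 1 the window is the full range and padj == probs anyway
    padj <- control$probs
    est <- stage("estimate_percentile_ri",
                 estimate_percentile_ri(kept, win, probs = padj,
                                        min_n = control$min_n))
    cis <- stage("bootstrap_ci",
                 bootstrap_ci(kept[inw], weights = NULL, probs = control$probs,
                              level = control$ci_level,
                              n_boot = control$n_boot, seed = seed,
                              adjusted_probs = padj, min_n = control$min_n))
    wts <- NULL
  }
  structure(list(
    lower = unname(est[1]), upper = unname(est[2]),
    lower_ci = cis$lower_ci, upper_ci = cis$upper_ci,
    n_input = n_input, n_after_outliers = length(kept),
    n_in_window = n_in_window,
    probs = control$probs, adjusted_probs = padj,
    transform = tr, mixture = mix, window = win,
    outliers = out$removed, estimator = control$estimator,
    control = control, seed = seed
  ), class = "ri_estimate")
}

#' @export
print.ri_estimate <- function(x, digits = 2, ...) {
  cat(sprintf("Indirect reference interval (central %.0f%%):\n",
              100 * diff(x$probs)))
  cat(sprintf("  %.*f - %.*f   [lower %.0f%% CI %.*f-%.*f; upper %.*f-%.*f]\n",
              digits, x$lower, digits, x$upper,
              100 * x$control$ci_level,
              digits, x$lower_ci[1], digits, x$lower_ci[2],
              digits, x$upper_ci[1], digits, x$upper_ci[2]))
  cat(sprintf("  n: %d input, %d after outliers, %d in window [%.3g, %.3g]\n",
              x$n_input, x$n_after_outliers, x$n_in_window,
              x$window$lower, x$window$upper))
  cat("  mixture k =", x$mixture$k, "|", x$transform$family,
      if (x$transform$family == "box_cox") paste("lambda", x$transform$lambda)
      else "", "| estimator", x$estimator, "\n")
  invisible(x)
}

#' Diagnostic plot of the fitted mixture and truncation window
#'
#' Histogram of the transformed, outlier-cleaned data overlaid with the
#' fitted mixture density, its components, and the truncation window.
#'
#' @param x an `ri_estimate` (must carry its `mixture` and `window`).
#' @param values the raw values the estimate was computed from.
#' @param ... passed to `hist()`.
#' @export
plot_ri_diagnostic <- function(x, values, ...) {
  v <- values[is.finite(values)]
  keep <- detect_outliers(v, x$control$fence_const, x$control$exp_lower,
                          x$control$exp_upper)$kept
  kt <- apply_transform(keep, x$transform)
  h <- graphics::hist(kt, breaks = 60, freq = FALSE,
                      main = "Mixture deconvolution",
                      xlab = "transformed analyte", ...)
  xs <- seq(min(kt), max(kt), length.out = 400)
  graphics::lines(xs, mixture_density(x$mixture, xs), lwd = 2)
  for (j in seq_len(x$mixture$k)) {
    graphics::lines(xs, x$mixture$weights[j] *
                      dnorm(xs, x$mixture$means[j], x$mixture$sds[j]),
                    lty = 2)
  }
  graphics::abline(v = c(x$window$lower_t, x$window$upper_t), col = 2, lwd = 2)
  invisible(h)
}
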
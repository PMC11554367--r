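#' Fit a Gaussian mixture by EM with BIC model selection
#'
#' Fits univariate Gaussian mixtures with k = 1..`k_max` components to the
#' (transformed-scale) values and returns the BIC-minimizing model. Each k
#' is fitted by EM to a relative log-likelihood tolerance of `tol`
#' (default 1e-8, at most `max_iter` iterations) from `n_restarts` seeded
#' restarts initialized at jittered quantile-spread locations; the best
#' restart by log-likelihood wins. The EM log-likelihood is monotone
#' non-decreasing by construction and is asserted every iteration when
#' `check_monotone = TRUE`.
#'
#' @param values_transformed numeric sample on the scale the mixture is
#'   assumed Gaussian on (usually after [select_transform()]); n >= 100.
#' @param k_max maximum number of components (>= 1).
#' @param seed integer seed controlling the restarts.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter EM iteration cap per restart.
#' @param n_restarts seeded restarts per k.
#' @param check_monotone assert the per-iteration monotone log-likelihood.
#' @return An object of class `mixture_model`: `k`, `weights`, `means`,
#'   `sds` (components sorted by mean), `loglik`, `bic`, `converged`,
#'   `n_iter`, plus `bic_by_k` for the scanned k values.
#' @export
#' @examples
#' set.seed(1)
#' fit_mixture(c(rnorm(300), rnorm(200, 6)), k_max = 3, seed = 1)
fit_mixture <- function(values_transformed, k_max = 4, seed = 1,
                        tol = 1e-8, max_iter = 1000, n_restarts = 5,
                        check_monotone = FALSE) {
  x <- values_transformed[is.finite(values_transformed)]
  n <- length(x)
  if (n < 100) stop("fit_mixture: need at least 100 values, got ", n,
                    call. = FALSE)
  if (k_max < 1) stop("fit_mixture: k_max must be >= 1", call. = FALSE)
  sdx <- sd(x)
  fits <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      set.seed(seed * 1000L + k * 10L + r)
      qs <- quantile(x, probs = pmin(pmax(
        (seq_len(k) - 0.5) / k + runif(k, -0.4, 0.4) / k, 0.001), 0.999),
        names = FALSE)
      f <- .em_gauss(x, rep(1 / k, k), as.numeric(qs), rep(sdx / k, k),
                     tol, max_iter, check_monotone)
      if (is.null(best) || f$loglik > best$loglik) best <- f
    }
    fits[[k]] <- best
  }
  bics <- vapply(seq_len(k_max), function(k) {
    -2 * fits[[k]]$loglik + (3 * k - 1) * log(n)
  }, numeric(1))
  k <- which.min(bics)
  f <- fits[[k]]
  if (!f$converged) {
    warning("fit_mixture: EM did not converge within ", max_iter,
            " iterations for the selected k = ", k, call. = FALSE)
  }
  o <- order(f$mu)
  structure(list(
    k = k,
    weights = f$w[o] / sum(f$w),
    means = f$mu[o],
    sds = f$sg[o],
    loglik = f$loglik,
    bic = bics[k],
    bic_by_k = bics,
    converged = f$converged,
    n_iter = f$n_iter,
    n = n
  ), class = "mixture_model")
}

#' Posterior responsibilities under a fitted mixture
#'
#' @param model a `mixture_model`.
#' @param x points on the model's (transformed) scale.
#' @param component component index; defaults to all.
#' @return A length(x) x k matrix of posterior membership probabilities
#'   (or a vector if `component` is given).
#' @export
responsibilities <- function(model, x, component = NULL) {
  k <- model$k
  d <- vapply(seq_len(k), function(j) {
    model$weights[j] * dnorm(x, model$means[j], model$sds[j])
  }, numeric(length(x)))
  if (length(x) == 1) d <- matrix(d, nrow = 1)
  tot <- rowSums(d)
  tot[tot < 1e-300] <- 1e-300
  r <- d / tot
  if (is.null(component)) r else r[, component]
}

#' Mixture density and component CDF helpers
#' @noRd
mixture_density <- function(model, x) {
  rowSums(vapply(seq_len(model$k), function(j) {
    model$weights[j] * dnorm(x, model$means[j], model$sds[j])
  }, numeric(length(x))))
}

#' @export
print.mixture_model <- function(x, ...) {
  cat("Gaussian mixture, k =", x$k,
      sprintf("(BIC %.1f, loglik %.1f, %s in %d iter)\n", x$bic, x$loglik,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  tab <- data.frame(weight = round(x$weights, 4),
                    mean = round(x$means, 4), sd = round(x$sds, 4))
  print(tab, row.names = FALSE)
  invisible(x)
}
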
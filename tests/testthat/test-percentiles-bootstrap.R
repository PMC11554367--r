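test_that("rank percentiles match the longhand oracle and quantile type 6", {
  vals <- as.numeric(1:39)
  expect_equal(unname(estimate_percentile_ri(vals, probs = c(0.025, 0.975),
                                             min_n = 20)),
               c(1, 39)) # ranks 1.0 and 39.0 exactly
  set.seed(15)
  x <- rlnorm(500, 1, 0.6)
  for (p in c(0.025, 0.1, 0.5, 0.9, 0.975)) {
    expect_equal(unname(estimate_percentile_ri(x, probs = p, min_n = 100)),
                 rank_percentile_oracle(x, p), tolerance = 1e-12)
    expect_equal(rank_percentile_oracle(x, p),
                 quantile(x, p, type = 6, names = FALSE), tolerance = 1e-12)
  }
  expect_error(estimate_percentile_ri(rnorm(50)), "at least 120")
})

test_that("large-sample percentiles approach the normal closed form", {
  set.seed(16)
  x <- rnorm(100000)
  ri <- estimate_percentile_ri(x)
  expect_equal(unname(ri), qnorm(c(0.025, 0.975)), tolerance = 0.02)
})

test_that("weighted rank quantile reduces to the plain estimator at unit weight", {
  set.seed(17)
  x <- rlnorm(400, 0, 0.5)
  for (p in c(0.025, 0.3, 0.975)) {
    expect_equal(weighted_rank_quantile(x, rep(1, 400), p),
                 rank_percentile_oracle(x, p), tolerance = 1e-12)
  }
  # zero-weight points do not move the estimate
  x2 <- c(x, 1e6)
  w2 <- c(rep(1, 400), 0)
  expect_equal(weighted_rank_quantile(x2, w2, 0.975),
               rank_percentile_oracle(x, 0.975), tolerance = 1e-9)
})

test_that("weighted quantiles target the component the weights describe", {
  # two overlapping Gaussians with known membership probabilities: the
  # responsibility-weighted quantile estimates the component quantile
  set.seed(18)
  n <- 40000
  nh <- rbinom(1, n, 0.7)
  x <- c(rnorm(nh, 0, 1), rnorm(n - nh, 3, 1))
  resp <- 0.7 * dnorm(x, 0, 1) /
    (0.7 * dnorm(x, 0, 1) + 0.3 * dnorm(x, 3, 1))
  est <- weighted_rank_quantile(x, resp, c(0.025, 0.975))
  expect_equal(est, qnorm(c(0.025, 0.975)), tolerance = 0.04)
})

test_that("bootstrap CIs are seed-deterministic and degenerate at n_boot = 1", {
  set.seed(19)
  x <- rlnorm(300, 1, 0.4)
  a <- bootstrap_ci(x, n_boot = 200, seed = 42)
  b <- bootstrap_ci(x, n_boot = 200, seed = 42)
  expect_identical(a, b)
  d <- bootstrap_ci(x, n_boot = 1, seed = 7)
  expect_equal(d$lower_ci[1], d$lower_ci[2])
  expect_equal(d$upper_ci[1], d$upper_ci[2])
  expect_error(bootstrap_ci(rnorm(50)), "at least 120")
})

test_that("bootstrap point clouds straddle the plain estimate", {
  set.seed(20)
  x <- rnorm(2000)
  ci <- bootstrap_ci(x, n_boot = 500, seed = 3)
  est <- estimate_percentile_ri(x)
  expect_lte(ci$lower_ci[1], est["lower"])
  expect_gte(ci$lower_ci[2], est["lower"])
  expect_lte(ci$upper_ci[1], est["upper"])
  expect_gte(ci$upper_ci[2], est["upper"])
})
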
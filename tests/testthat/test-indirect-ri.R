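test_that("a clean lognormal healthy sample is recovered within 5%", {
  spec <- clean_spec(n = 20000, seed = 30)
  co <- generate_cohort(spec)
  ri <- suppressWarnings(run_indirect_ri(co$insulin,
                                         ri_control(n_boot = 200), seed = 1))
  tru <- true_healthy_quantiles(spec, "all")
  expect_lt(abs(ri$lower / tru[1] - 1), 0.05)
  expect_lt(abs(ri$upper / tru[2] - 1), 0.05)
  expect_true(ri$n_input >= ri$n_after_outliers)
  expect_true(ri$n_after_outliers >= ri$n_in_window)
})

test_that("truncation shields the upper bound from contamination", {
  clean <- generate_cohort(clean_spec(n = 20000, seed = 31))
  dirty <- generate_cohort(contaminated_spec(n = 20000, seed = 31))
  ctl <- ri_control(n_boot = 100)
  ri_clean <- run_indirect_ri(clean$insulin, ctl, seed = 2)
  ri_dirty <- run_indirect_ri(dirty$insulin, ctl, seed = 2)
  # pipeline: contamination moves the upper bound < 10%
  expect_lt(abs(ri_dirty$upper / ri_clean$upper - 1), 0.10)
  # naive untruncated percentiles: pushed far upward (> 25%)
  naive <- estimate_percentile_ri(dirty$insulin)
  expect_gt(naive["upper"] / ri_clean$upper - 1, 0.25)
})

test_that("the estimate is invariant to input permutation", {
  set.seed(32)
  x <- generate_cohort(contaminated_spec(n = 3000, seed = 33))$insulin
  ctl <- ri_control(n_boot = 50)
  a <- run_indirect_ri(x, ctl, seed = 5)
  b <- run_indirect_ri(sample(x), ctl, seed = 5)
  expect_identical(c(a$lower, a$upper), c(b$lower, b$upper))
  expect_identical(a$lower_ci, b$lower_ci)
})

test_that("with k_max = 1 the pipeline equals plain percentiles exactly", {
  set.seed(34)
  x <- rlnorm(5000, log(6), 0.4)
  ri <- run_indirect_ri(x, ri_control(k_max = 1, n_boot = 50), seed = 1)
  kept <- detect_outliers(x)$kept
  expect_equal(c(ri$lower, ri$upper),
               quantile(kept, c(0.025, 0.975), type = 6, names = FALSE),
               tolerance = 1e-12)
  expect_equal(ri$mixture$k, 1)
  expect_equal(ri$window$source, c("data_extreme", "data_extreme"))
})

test_that("RI bounds are equivariant under positive affine maps (identity scale)", {
  set.seed(35)
  x <- rnorm(5000, 50, 4) # symmetric: transform gate keeps identity
  ctl <- ri_control(n_boot = 20)
  base <- run_indirect_ri(x, ctl, seed = 3)
  shifted <- run_indirect_ri(2.5 * x + 10, ctl, seed = 3)
  expect_equal(base$transform$family, "identity")
  expect_equal(c(shifted$lower, shifted$upper),
               2.5 * c(base$lower, base$upper) + 10, tolerance = 1e-6)
})

test_that("point estimates are stable across EM/bootstrap seeds", {
  x <- generate_cohort(contaminated_spec(n = 20000, seed = 36))$insulin
  ctl <- ri_control(n_boot = 20)
  ests <- vapply(1:4, function(s) {
    ri <- run_indirect_ri(x, ctl, seed = s)
    c(ri$lower, ri$upper)
  }, numeric(2))
  spread <- apply(ests, 1, function(v) diff(range(v)) / mean(v))
  expect_lt(max(spread), 0.005)
})

test_that("small samples warn and stage errors carry the stage name", {
  expect_warning(run_indirect_ri(rlnorm(450, 1, 0.3),
                                 ri_control(n_boot = 10), seed = 1),
                 "below the recommended")
  expect_error(suppressWarnings(run_indirect_ri(rnorm(19))),
               "detect_outliers")
})
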
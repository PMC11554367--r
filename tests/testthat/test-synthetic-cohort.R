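test_that("generation is deterministic and honours the female rounding rule", {
  spec <- contaminated_spec(n = 20000, seed = 7)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)
  expect_equal(sum(a$sex == "F"), 17200) # round(20000 * 0.86)
  expect_equal(nrow(a), 20000)
})

test_that("degenerate spec with healthy_fraction = 1 labels everyone healthy", {
  co <- generate_cohort(clean_spec(n = 500, seed = 3))
  expect_true(all(co$is_healthy_truth))
})

test_that("invalid specs name the offending field", {
  expect_error(cohort_spec(female_fraction = 1.2), "female_fraction")
  expect_error(cohort_spec(age_range = c(18, 60)), "age_range")
  expect_error(cohort_spec(insulin_healthy_logsd_f = -0.1),
               "insulin_healthy_logsd_f")
})

test_that("analyte values are strictly positive and heights plausible", {
  co <- generate_cohort(contaminated_spec(n = 5000, seed = 9))
  for (col in c("insulin", "glucose", "a1c", "hdl", "tg", "weight")) {
    expect_true(all(co[[col]] > 0), label = paste(col, "positive"))
  }
  expect_true(all(co$height > 1.2 & co$height < 2.2))
})

test_that("true healthy quantiles match the lognormal closed form", {
  spec <- cohort_spec(insulin_healthy_logmean_f = log(5.8),
                      insulin_healthy_logsd_f = 0.42)
  expect_equal(true_healthy_quantiles(spec, "F", c(0.025, 0.975)),
               exp(log(5.8) + qnorm(c(0.025, 0.975)) * 0.42))
  # zero-variance medians collapse to the geometric mean
  s0 <- cohort_spec(insulin_healthy_logmean_f = log(5.8),
                    insulin_healthy_logsd_f = 0)
  expect_equal(true_healthy_quantiles(s0, "F", 0.5), 5.8)
  # identical F/M parameters: pooled quantile equals the single-sex one
  sm <- cohort_spec(insulin_healthy_logmean_m = log(5.8),
                    insulin_healthy_logsd_m = 0.42,
                    insulin_healthy_logmean_f = log(5.8),
                    insulin_healthy_logsd_f = 0.42)
  expect_equal(true_healthy_quantiles(sm, "all", c(0.1, 0.9)),
               true_healthy_quantiles(sm, "F", c(0.1, 0.9)),
               tolerance = 1e-8)
})

test_that("pooled-sex quantiles agree with Monte Carlo at 1e6 draws", {
  spec <- cohort_spec()
  set.seed(42)
  n <- 1e6
  nf <- rbinom(1, n, spec$female_fraction)
  draws <- c(rlnorm(nf, spec$insulin_healthy_logmean_f,
                    spec$insulin_healthy_logsd_f),
             rlnorm(n - nf, spec$insulin_healthy_logmean_m,
                    spec$insulin_healthy_logsd_m))
  mc <- quantile(draws, c(0.025, 0.975), names = FALSE)
  expect_equal(true_healthy_quantiles(spec, "all", c(0.025, 0.975)), mc,
               tolerance = 0.01)
})

test_that("empirical healthy quantiles converge to the analytic truth", {
  spec <- contaminated_spec(n = 50000, seed = 21)
  co <- generate_cohort(spec)
  healthy_f <- co$insulin[co$is_healthy_truth & co$sex == "F"]
  emp <- quantile(healthy_f, c(0.025, 0.5, 0.975), names = FALSE)
  tru <- true_healthy_quantiles(spec, "F", c(0.025, 0.5, 0.975))
  expect_true(all(abs(emp / tru - 1) < 0.02))
})

test_that("medication prevalence follows the law of total probability", {
  spec <- contaminated_spec(n = 50000, seed = 22)
  co <- generate_cohort(spec)
  p <- spec$healthy_fraction * spec$medication_prob_given_health +
    (1 - spec$healthy_fraction) * spec$medication_prob_given_pathology
  observed <- mean(co$medications != "")
  half_width <- qnorm(0.995) * sqrt(p * (1 - p) / nrow(co))
  expect_lt(abs(observed - p), half_width)
})

test_that("cohort CSV round-trips records and provenance", {
  spec <- clean_spec(n = 200, seed = 5)
  co <- generate_cohort(spec)
  path <- tempfile(fileext = ".csv")
  write_cohort_csv(co, path, spec = spec)
  back <- read_cohort_csv(path)
  expect_equal(back$insulin, co$insulin, tolerance = 1e-12)
  expect_equal(back$medications, co$medications)
  prov <- jsonlite::read_json(paste0(path, ".provenance.json"))
  expect_equal(prov$seed, 5)
  unlink(c(path, paste0(path, ".provenance.json")))
})
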
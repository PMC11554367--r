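test_that("BMI arithmetic is exact and rejects non-positive input", {
  expect_equal(compute_bmi(81, 1.80), 25.0)
  expect_equal(compute_bmi(60, 2.00), 15.0)
  expect_equal(compute_bmi(70, 1.723), 70 / 1.723^2)
  expect_error(compute_bmi(-1, 1.7), "positive")
  expect_error(compute_bmi(70, 0), "positive")
})

test_that("boundary records fall on the documented side of each threshold", {
  base <- data.frame(
    subject_id = "X", sex = "F", age = 30, weight = 60, height = 1.60,
    insulin = 6, glucose = 99, a1c = 5.6, hdl = 50, tg = 149,
    medications = "", yearly_exam_count = 1, stringsAsFactors = FALSE
  )
  res <- apply_exclusions(base)
  expect_equal(res$audit$n_retained, 1) # every threshold just missed

  at_bmi <- base
  at_bmi$weight <- 100 # with height 2.00: BMI exactly 25.0 -> excluded
  at_bmi$height <- 2.00
  res <- apply_exclusions(at_bmi)
  expect_equal(res$audit$n_retained, 0)
  expect_equal(res$audit$excluded_by_criterion$bmi, 1)

  at_glu <- base
  at_glu$glucose <- 100
  expect_equal(apply_exclusions(at_glu)$audit$excluded_by_criterion$glucose, 1)
})

test_that("the packaged 12-record fixture retains exactly the hand-derived set", {
  fixture <- read_cohort_csv(system.file("extdata", "filter_fixture.csv",
                                         package = "insulinRI"))
  res <- apply_exclusions(fixture)
  expect_equal(res$audit$n_retained, 5)
  expect_setequal(res$retained$subject_id, c("P01", "P07", "P10", "P11", "P12"))
  expect_equal(res$audit$excluded_by_criterion$bmi, 2)
  expect_equal(res$audit$excluded_by_criterion$glucose, 1)
  expect_equal(res$audit$excluded_by_criterion$a1c, 1)
  expect_equal(res$audit$excluded_by_criterion$tg, 1)
  expect_equal(res$audit$excluded_by_criterion$hdl, 1)
  expect_equal(res$audit$excluded_by_criterion$medication, 1)
})

test_that("audit conserves counts and the filter is idempotent", {
  for (seed in c(1, 2, 3)) {
    co <- generate_cohort(contaminated_spec(n = 1000, seed = seed))
    res <- apply_exclusions(co)
    expect_equal(res$audit$n_input,
                 res$audit$n_retained +
                   sum(unlist(res$audit$excluded_by_criterion)))
    again <- apply_exclusions(res$retained)
    expect_equal(again$audit$n_retained, nrow(res$retained))
    expect_equal(sum(unlist(again$audit$excluded_by_criterion)), 0)
  }
})

test_that("retained records are enriched for true health but not pure", {
  co <- generate_cohort(contaminated_spec(n = 20000, seed = 4))
  res <- apply_exclusions(co)
  enrichment <- mean(res$retained$is_healthy_truth) / mean(co$is_healthy_truth)
  expect_gt(enrichment, 1)
  expect_gt(sum(!res$retained$is_healthy_truth), 0) # filtering is imperfect
})

test_that("missing fields and unknown sex codes exclude under missing_data", {
  co <- generate_cohort(clean_spec(n = 10, seed = 6))
  co$glucose[3] <- NA
  co$sex[5] <- "U"
  expect_warning(res <- apply_exclusions(co), "unknown sex")
  expect_equal(res$audit$excluded_by_criterion$missing_data, 2)
  expect_false(any(c(co$subject_id[3], co$subject_id[5]) %in%
                     res$retained$subject_id))
})

test_that("dedupe removes frequent visitors and keeps the earliest visit", {
  rec <- function(id, date) {
    data.frame(subject_id = id, sex = "F", age = 30, weight = 60,
               height = 1.6, insulin = 6, glucose = 90, a1c = 5,
               hdl = 60, tg = 80, medications = "", yearly_exam_count = 1,
               visit_date = date, stringsAsFactors = FALSE)
  }
  records <- rbind(
    rec("A", "2019-03-01"), rec("A", "2019-07-01"), rec("A", "2019-11-01"),
    rec("B", "2019-06-15"), rec("B", "2019-02-10"),
    rec("C", "2019-05-05")
  )
  out <- dedupe_subjects(records)
  expect_false("A" %in% out$subject_id) # 3 visits: removed entirely
  expect_equal(out$visit_date[out$subject_id == "B"], "2019-02-10")
  expect_equal(nrow(out[out$subject_id == "C", ]), 1)
})
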
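# a small but estimable study configuration used across report tests
report_spec <- function(seed = 50) contaminated_spec(n = 6000, seed = seed)
report_ctl <- function() ri_control(n_boot = 50)

test_that("run_study produces a consistent, schema-complete report", {
  rep <- suppressWarnings(
    run_study(report_spec(), control = report_ctl(), seed = 1)
  )
  expect_s3_class(rep, "study_report")
  expect_named(rep$ri_table, c("insulin", "homa_ir"))
  expect_named(rep$ri_table$insulin, c("F", "M", "all"))
  # group n consistency: sexes partition the retained cohort
  nf <- rep$cohort_summary$insulin$female$n
  nm <- rep$cohort_summary$insulin$male$n
  expect_equal(nf + nm, rep$provenance$n_retained)
  expect_equal(sum(rep$age_strata$n), rep$provenance$n_retained)
  # every group RI is ordered
  for (a in names(rep$ri_table)) {
    for (g in names(rep$ri_table[[a]])) {
      ri <- rep$ri_table[[a]][[g]]
      expect_lt(ri$lower, ri$upper)
    }
  }
})

test_that("reports are deterministic and CSV input equals in-memory input", {
  spec <- report_spec(51)
  r1 <- suppressWarnings(run_study(spec, control = report_ctl(), seed = 2))
  r2 <- suppressWarnings(run_study(spec, control = report_ctl(), seed = 2))
  expect_identical(render_report(r1, "json"), render_report(r2, "json"))

  co <- generate_cohort(spec)
  path <- tempfile(fileext = ".csv")
  write_cohort_csv(co, path)
  r3 <- suppressWarnings(run_study(path, control = report_ctl(), seed = 2))
  expect_equal(r3$ri_table$insulin$all$lower, r1$ri_table$insulin$all$lower,
               tolerance = 1e-9)
  unlink(path)
})

test_that("identical F/M generator parameters give a no-partition verdict", {
  spec <- contaminated_spec(
    n = 6000, seed = 52,
    insulin_healthy_logmean_m = log(5.8), insulin_healthy_logsd_m = 0.42,
    hdl_healthy_mean_m = 62, hdl_healthy_sd_m = 10
  )
  rep <- suppressWarnings(run_study(spec, control = report_ctl(), seed = 3))
  expect_false(rep$partition$insulin$partition_required)
  expect_false(rep$partition$homa_ir$partition_required)
})

test_that("rendered formats are faithful views of the report", {
  rep <- suppressWarnings(run_study(report_spec(53), control = report_ctl(),
                                    seed = 4))
  js <- render_report(rep, "json")
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$ri_table$insulin$all$lower, rep$ri_table$insulin$all$lower,
               tolerance = 1e-12)
  expect_equal(parsed$provenance$seed, 4)

  md <- render_report(rep, "markdown")
  ri_rows <- grep("^\\| (insulin|homa_ir) \\| (F|M|all) \\|",
                  strsplit(md, "\n")[[1]])
  expect_length(ri_rows, 6) # 2 analytes x 3 groups

  cs <- render_report(rep, "csv")
  expect_equal(nrow(cs), 6)
  expect_true(is.numeric(cs$lower) && is.numeric(cs$upper))
  expect_error(render_report(rep, "pdf"))
})
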
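#' Run the full indirect-RI study on a cohort
#'
#' Orchestrates the complete workflow: generate (or read) the cohort,
#' deduplicate repeat visits, apply the exclusion criteria, append
#' HOMA-IR, estimate the reference interval for fasting insulin and
#' HOMA-IR in women, men and the pooled population, and run the
#' Harris-Boyd partitioning decision (on the transformed scale) plus the
#' Mann-Whitney group comparison for each analyte.
#'
#' @param cohort_source a [cohort_spec()], a cohort data.frame, or a path
#'   to a cohort CSV.
#' @param config an [exclusion_config()].
#' @param control an [ri_control()].
#' @param convention a [unit_convention()].
#' @param seed integer seed for the RI estimations.
#' @param groups which groups to estimate; default female, male, all.
#' @return An object of class `study_report` with elements
#'   `cohort_summary` (per-sex medians/ranges with Mann-Whitney p values),
#'   `age_strata` (medians by decade band), `ri_table` (per group x
#'   analyte `ri_estimate`s), `partition` (per analyte
#'   `partition_decision`), `audit`, and `provenance`.
#' @export
run_study <- function(cohort_source, config = exclusion_config(),
                      control = ri_control(),
                      convention = unit_convention(), seed = 1,
                      groups = c("F", "M", "all")) {
  cohort <- if (inherits(cohort_source, "cohort_spec")) {
    generate_cohort(cohort_source)
  } else if (is.character(cohort_source)) {
    read_cohort_csv(cohort_source)
  } else {
    cohort_source
  }
  cohort <- dedupe_subjects(cohort, config$max_yearly_exams)
  flt <- apply_exclusions(cohort, config)
  retained <- add_homa(flt$retained, convention)

  sex_split <- split(retained, retained$sex)
  getg <- function(g, col) {
    if (g == "all") retained[[col]] else sex_split[[g]][[col]]
  }

  summarize_var <- function(col, digits = 6) {
    f <- sex_split[["F"]][[col]]
    m <- sex_split[["M"]][[col]]
    mw <- if (length(f) > 0 && length(m) > 0) mann_whitney(f, m) else
      list(U = NA_real_, p = NA_real_)
    list(
      female = list(median = median(f), range = range(f), n = length(f)),
      male = list(median = median(m), range = range(m), n = length(m)),
      p_value = mw$p
    )
  }
  summary_vars <- c("age", "insulin", "glucose", "hdl", "a1c", "tg",
                    "homa_ir")
  retained$bmi <- compute_bmi(retained$weight, retained$height)
  sex_split <- split(retained, retained$sex)
  cohort_summary <- lapply(setNames(c(summary_vars, "bmi"),
                                    c(summary_vars, "bmi")), summarize_var)

  bands <- cut(retained$age, c(20, 30, 40, 50, 60.0001), right = FALSE,
               labels = c("20-29", "30-39", "40-49", "50-60"))
  strata_of <- function(col) {
    vapply(levels(bands), function(b) {
      median(retained[[col]][bands == b])
    }, numeric(1))
  }
  age_strata <- list(
    n = as.integer(table(bands)),
    bands = levels(bands),
    bmi = strata_of("bmi"), insulin = strata_of("insulin"),
    glucose = strata_of("glucose"), tg = strata_of("tg"),
    hdl = strata_of("hdl")
  )

  ri_table <- list()
  for (analyte in c("insulin", "homa_ir")) {
    for (g in groups) {
      v <- getg(g, analyte)
      ri_table[[analyte]][[g]] <- run_indirect_ri(v, control, seed = seed)
    }
  }

  partition <- list()
  for (analyte in c("insulin", "homa_ir")) {
    f <- sex_split[["F"]][[analyte]]
    m <- sex_split[["M"]][[analyte]]
    # symmetrize jointly so both groups live on one scale
    tr <- select_transform(c(f, m), control$skew_gate, control$kurt_gate)
    partition[[analyte]] <- harris_boyd(apply_transform(f, tr),
                                        apply_transform(m, tr))
  }

  structure(list(
    cohort_summary = cohort_summary,
    age_strata = age_strata,
    ri_table = ri_table,
    partition = partition,
    audit = flt$audit,
    provenance = list(
      schema_version = "1.0",
      seed = seed,
      convention = convention$name,
      n_input = flt$audit$n_input,
      n_retained = flt$audit$n_retained,
      config = unclass(config),
      control = unclass(control),
      package_version = as.character(utils::packageVersion("insulinRI"))
    )
  ), class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("Indirect RI study report:", x$provenance$n_input, "records in,",
      x$provenance$n_retained, "retained\n")
  for (analyte in names(x$ri_table)) {
    for (g in names(x$ri_table[[analyte]])) {
      ri <- x$ri_table[[analyte]][[g]]
      cat(sprintf("  %-8s %-4s %.2f - %.2f (n = %d)\n", analyte, g,
                  ri$lower, ri$upper, ri$n_in_window))
    }
  }
  for (analyte in names(x$partition)) {
    cat(sprintf("  partition[%s]: %s\n", analyte,
                if (x$partition[[analyte]]$partition_required) "PARTITION"
                else "common interval"))
  }
  invisible(x)
}

ri_row <- function(ri, digits = 2) {
  list(lower = round(ri$lower, digits), upper = round(ri$upper, digits),
       lower_ci = round(ri$lower_ci, digits),
       upper_ci = round(ri$upper_ci, digits), n = ri$n_in_window)
}

report_to_list <- function(report) {
  list(
    schema_version = report$provenance$schema_version,
    cohort_summary = report$cohort_summary,
    age_strata = report$age_strata,
    ri_table = lapply(report$ri_table, function(by_group) {
      lapply(by_group, function(ri) {
        list(lower = ri$lower, upper = ri$upper,
             lower_ci = ri$lower_ci, upper_ci = ri$upper_ci,
             n_input = ri$n_input, n_after_outliers = ri$n_after_outliers,
             n_in_window = ri$n_in_window, probs = ri$probs,
             transform = unclass(ri$transform),
             mixture = unclass(ri$mixture)[c("k", "weights", "means", "sds",
                                             "loglik", "bic", "converged",
                                             "n_iter")],
             window = unclass(ri$window)[c("lower", "upper", "source")],
             estimator = ri$estimator, seed = ri$seed)
      })
    }),
    partition = lapply(report$partition, unclass),
    audit = unclass(report$audit),
    provenance = report$provenance
  )
}

#' Render a study report as JSON, markdown or CSV
#'
#' JSON is the lossless machine-readable form (the full provenance makes
#' every number reproducible from the document alone); markdown and CSV
#' are presentation views of the cohort-characteristics, age-strata and
#' reference-interval tables, rounded per the display conventions (2
#' decimals for HOMA-IR and RI bounds, 1 for converted analytes).
#'
#' @param report a `study_report`.
#' @param format `"json"`, `"markdown"` or `"csv"`.
#' @param path optional file to write to.
#' @return The rendered document as a character scalar (JSON/markdown) or
#'   data.frame (CSV), invisibly if `path` is given.
#' @export
render_report <- function(report, format = c("json", "markdown", "csv"),
                          path = NULL) {
  format <- match.arg(format)
  out <- switch(format,
    json = jsonlite::toJSON(report_to_list(report), auto_unbox = TRUE,
                            digits = NA, null = "null"),
    markdown = render_markdown(report),
    csv = render_csv(report)
  )
  if (!is.null(path)) {
    if (format == "csv") write.csv(out, path, row.names = FALSE)
    else writeLines(as.character(out), path)
    return(invisible(out))
  }
  out
}

render_markdown <- function(report) {
  L <- character(0)
  add <- function(...) L <<- c(L, paste0(...))
  add("# Indirect reference-interval study report")
  add("")
  add("## Cohort characteristics (retained records)")
  add("")
  add("| Variable | Women (median, range) | Men (median, range) | P |")
  add("|---|---|---|---|")
  fmt_grp <- function(g, d = 2) {
    sprintf("%.*f (%.*f-%.*f)", d, g$median, d, g$range[1], d, g$range[2])
  }
  for (v in names(report$cohort_summary)) {
    s <- report$cohort_summary[[v]]
    add(sprintf("| %s | %s | %s | %.3g |", v, fmt_grp(s$female),
                fmt_grp(s$male), s$p_value))
  }
  add("")
  add("## Medians by age band")
  add("")
  add("| Age | n | BMI | Insulin | Glucose | Tg | HDL-c |")
  add("|---|---|---|---|---|---|---|")
  st <- report$age_strata
  for (i in seq_along(st$bands)) {
    add(sprintf("| %s | %d | %.1f | %.2f | %.0f | %.0f | %.0f |",
                st$bands[i], st$n[i], st$bmi[i], st$insulin[i],
                st$glucose[i], st$tg[i], st$hdl[i]))
  }
  add("")
  add("## Reference intervals (central 95%, 90% CIs)")
  add("")
  add("| Analyte | Group | n | RI | Lower CI | Upper CI |")
  add("|---|---|---|---|---|---|")
  for (analyte in names(report$ri_table)) {
    for (g in names(report$ri_table[[analyte]])) {
      r <- ri_row(report$ri_table[[analyte]][[g]])
      add(sprintf("| %s | %s | %d | %.2f-%.2f | %.2f-%.2f | %.2f-%.2f |",
                  analyte, g, r$n, r$lower, r$upper, r$lower_ci[1],
                  r$lower_ci[2], r$upper_ci[1], r$upper_ci[2]))
    }
  }
  add("")
  add("## Partitioning")
  add("")
  for (analyte in names(report$partition)) {
    p <- report$partition[[analyte]]
    add(sprintf("- %s: %s (%s)", analyte,
                if (p$partition_required) "sex-specific intervals"
                else "common interval", p$rationale))
  }
  paste(L, collapse = "\n")
}

render_csv <- function(report) {
  rows <- list()
  for (analyte in names(report$ri_table)) {
    for (g in names(report$ri_table[[analyte]])) {
      ri <- report$ri_table[[analyte]][[g]]
      rows[[length(rows) + 1]] <- data.frame(
        analyte = analyte, group = g, n = ri$n_in_window,
        lower = ri$lower, upper = ri$upper,
        lower_ci_lo = ri$lower_ci[1], lower_ci_hi = ri$lower_ci[2],
        upper_ci_lo = ri$upper_ci[1], upper_ci_hi = ri$upper_ci[2],
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
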
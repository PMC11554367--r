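#' Exclusion criteria configuration
#'
#' Encodes the health-screening exclusion criteria applied before indirect
#' RI estimation. The defaults exclude: BMI < 18.5 or >= 25 kg/m^2,
#' glucose >= 100 mg/dL, A1C >= 5.7%, triglycerides >= 150 mg/dL,
#' HDL-c < 50 (women) / < 40 (men) mg/dL, use of antidiabetic,
#' lipid-lowering or antihypertensive medication, more than 2 yearly exams,
#' and age outside 20-60 years. Inclusion is the strict complement of each
#' exclusion threshold: glucose 99 is retained, 100 excluded; HDL exactly at
#' the sex minimum is retained.
#'
#' @param bmi_low inclusive lower BMI bound for retention, kg/m^2.
#' @param bmi_high exclusive upper BMI bound, kg/m^2.
#' @param glucose_max exclusive upper glucose bound, mg/dL.
#' @param a1c_max exclusive upper A1C bound, %.
#' @param tg_max exclusive upper triglycerides bound, mg/dL.
#' @param hdl_min_f,hdl_min_m inclusive lower HDL-c bound by sex, mg/dL.
#' @param excluded_medication_classes medication classes that exclude.
#' @param max_yearly_exams maximum permitted yearly exam count.
#' @param age_min,age_max inclusive age window, years.
#' @param criterion_order order in which criteria are checked; a record is
#'   attributed to the first failing criterion.
#' @return An object of class `exclusion_config`.
#' @export
exclusion_config <- function(bmi_low = 18.5, bmi_high = 25,
                             glucose_max = 100, a1c_max = 5.7, tg_max = 150,
                             hdl_min_f = 50, hdl_min_m = 40,
                             excluded_medication_classes = c(
                               "antidiabetic", "lipid_lowering",
                               "antihypertensive"
                             ),
                             max_yearly_exams = 2,
                             age_min = 20, age_max = 60,
                             criterion_order = c(
                               "missing_data", "age", "bmi", "glucose", "a1c",
                               "tg", "hdl", "medication", "yearly_exams"
                             )) {
  stopifnot(bmi_low < bmi_high, bmi_low > 0, glucose_max > 0, a1c_max > 0,
            tg_max > 0, hdl_min_f > 0, hdl_min_m > 0, max_yearly_exams > 0)
  structure(list(
    bmi_low = bmi_low, bmi_high = bmi_high, glucose_max = glucose_max,
    a1c_max = a1c_max, tg_max = tg_max, hdl_min_f = hdl_min_f,
    hdl_min_m = hdl_min_m,
    excluded_medication_classes = excluded_medication_classes,
    max_yearly_exams = max_yearly_exams, age_min = age_min, age_max = age_max,
    criterion_order = criterion_order
  ), class = "exclusion_config")
}

#' Body mass index
#'
#' @param weight weight in kg, > 0.
#' @param height height in m, > 0.
#' @return BMI in kg/m^2.
#' @export
#' @examples
#' compute_bmi(81, 1.80) # 25.0
compute_bmi <- function(weight, height) {
  if (any(!is.finite(weight)) || any(!is.finite(height)) ||
      any(weight <= 0) || any(height <= 0)) {
    stop("compute_bmi: weight and height must be finite and positive",
         call. = FALSE)
  }
  weight / height^2
}

# per-record failure indicator for one named criterion; NA fields never
# reach here (missing_data fires first)
criterion_fails <- function(records, criterion, config) {
  switch(criterion,
    age = records$age < config$age_min | records$age > config$age_max,
    bmi = {
      bmi <- records$weight / records$height^2
      bmi < config$bmi_low | bmi >= config$bmi_high
    },
    glucose = records$glucose >= config$glucose_max,
    a1c = records$a1c >= config$a1c_max,
    tg = records$tg >= config$tg_max,
    hdl = ifelse(records$sex == "F",
                 records$hdl < config$hdl_min_f,
                 records$hdl < config$hdl_min_m),
    medication = vapply(strsplit(ifelse(is.na(records$medications), "",
                                        records$medications), ","),
                        function(m) any(trimws(m) %in%
                                          config$excluded_medication_classes),
                        logical(1)),
    yearly_exams = records$yearly_exam_count > config$max_yearly_exams,
    stop("unknown criterion: ", criterion, call. = FALSE)
  )
}

fields_needed <- c("sex", "age", "weight", "height", "glucose", "a1c",
                   "hdl", "tg", "yearly_exam_count")

#' Apply exclusion criteria with a per-criterion audit
#'
#' Retains a record iff it passes every active criterion; each excluded
#' record is counted under the first failing criterion in
#' `config$criterion_order`, so the audit counts always sum to the number
#' excluded (`n_input = n_retained + sum(excluded_by_criterion)`). Records
#' with missing required fields or an unknown sex code are excluded under
#' `"missing_data"` (the latter with a warning).
#'
#' @param records cohort data.frame (see [generate_cohort()] for columns).
#' @param config an [exclusion_config()].
#' @return A list with `retained` (data.frame) and `audit` (class
#'   `filter_audit`: `n_input`, `n_retained`, `excluded_by_criterion`,
#'   `criterion_order`).
#' @export
apply_exclusions <- function(records, config = exclusion_config()) {
  n <- nrow(records)
  order_ <- config$criterion_order
  missing_cols <- setdiff(fields_needed, names(records))
  incomplete <- rep(length(missing_cols) > 0, n)
  if (!any(incomplete) && n > 0) {
    incomplete <- Reduce(`|`, lapply(fields_needed, function(f) {
      is.na(records[[f]])
    }))
  }
  bad_sex <- !is.na(records$sex) & !(records$sex %in% c("F", "M"))
  if (any(bad_sex)) {
    warning(sum(bad_sex), " record(s) with unknown sex code excluded under ",
            "'missing_data'", call. = FALSE)
  }
  incomplete <- incomplete | bad_sex

  assigned <- rep(NA_character_, n)
  assigned[incomplete] <- "missing_data"
  for (crit in setdiff(order_, "missing_data")) {
    todo <- is.na(assigned)
    if (!any(todo)) break
    fails <- criterion_fails(records[todo, , drop = FALSE], crit, config)
    assigned[which(todo)[fails]] <- crit
  }
  retained <- records[is.na(assigned), , drop = FALSE]
  counts <- table(factor(assigned[!is.na(assigned)], levels = order_))
  audit <- structure(list(
    n_input = n,
    n_retained = nrow(retained),
    excluded_by_criterion = as.list(setNames(as.integer(counts),
                                             names(counts))),
    criterion_order = order_
  ), class = "filter_audit")
  list(retained = retained, audit = audit)
}

#' @export
print.filter_audit <- function(x, ...) {
  cat("Exclusion audit:", x$n_input, "in,", x$n_retained, "retained\n")
  shown <- Filter(function(v) v > 0, x$excluded_by_criterion)
  for (nm in names(shown)) cat(sprintf("  %-14s %d\n", nm, shown[[nm]]))
  invisible(x)
}

#' Deduplicate repeat-visit subjects
#'
#' Subjects with more than `max_yearly_exams` visits are removed entirely
#' (frequent testing flags likely illness); for the remaining subjects only
#' the earliest visit is kept, ordered by `visit_date` when present, else
#' by row order.
#'
#' @param records cohort data.frame, possibly with repeated `subject_id`.
#' @param max_yearly_exams visit-count cutoff for total removal.
#' @return A data.frame with at most one row per retained subject.
#' @export
dedupe_subjects <- function(records, max_yearly_exams = 2) {
  if (nrow(records) == 0) return(records)
  visits <- table(records$subject_id)
  keep_ids <- names(visits)[visits <= max_yearly_exams]
  out <- records[records$subject_id %in% keep_ids, , drop = FALSE]
  if (nrow(out) == 0) return(out)
  ord <- if ("visit_date" %in% names(out)) {
    order(out$subject_id, as.Date(out$visit_date))
  } else {
    order(out$subject_id, seq_len(nrow(out)))
  }
  out <- out[ord, , drop = FALSE]
  out <- out[!duplicated(out$subject_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
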
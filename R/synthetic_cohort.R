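#' Specify a synthetic laboratory cohort
#'
#' Defines the generative model for a synthetic LIS-style cohort: a dominant
#' healthy subpopulation with right-skewed (lognormal) fasting insulin,
#' contaminated by one or more pathological subpopulations whose insulin,
#' glucose, BMI, A1C and lipids are shifted upward (HDL-c downward) and whose
#' medication use is more likely. The healthy insulin component has
#' closed-form quantiles (see [true_healthy_quantiles()]), so downstream
#' estimators can be scored against known truth.
#'
#' Component weights are normalized on construction so that
#' `healthy_fraction` plus the pathological weights sum to 1.
#'
#' @param n_subjects number of subjects.
#' @param female_fraction fraction of females; the female count is
#'   `round(n_subjects * female_fraction)`.
#' @param healthy_fraction prior probability that a subject is healthy.
#' @param insulin_healthy_logmean_f,insulin_healthy_logsd_f lognormal
#'   parameters (log uU/mL scale) of healthy female fasting insulin.
#' @param insulin_healthy_logmean_m,insulin_healthy_logsd_m same for males.
#' @param pathological_components list of `c(weight=, logmean=, logsd=)`
#'   insulin components for the pathological contamination.
#' @param glucose_healthy_mean,glucose_healthy_sd healthy fasting glucose,
#'   mg/dL.
#' @param bmi_healthy_mean,bmi_healthy_sd healthy BMI, kg/m^2.
#' @param a1c_healthy_mean,a1c_healthy_sd healthy hemoglobin A1C, %.
#' @param tg_healthy_logmean,tg_healthy_logsd healthy triglycerides,
#'   lognormal on log mg/dL.
#' @param hdl_healthy_mean_f,hdl_healthy_sd_f,hdl_healthy_mean_m,hdl_healthy_sd_m
#'   healthy HDL-c, mg/dL, by sex.
#' @param pathology_shift_multipliers named multipliers applied to
#'   pathological members' glucose, bmi, a1c, tg and hdl draws.
#' @param medication_prob_given_pathology,medication_prob_given_health
#'   probability that a subject reports at least one excluded medication
#'   class, by health status.
#' @param glucose_insulin_rho latent Gaussian correlation between healthy
#'   log-insulin and glucose, so HOMA-IR varies realistically.
#' @param age_range inclusive age window in years, within 20-60.
#' @param seed integer seed; generation is deterministic given the spec.
#'
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()], [true_healthy_quantiles()]
#' @export
#' @examples
#' spec <- cohort_spec(n_subjects = 500, seed = 1)
#' cohort <- generate_cohort(spec)
#' head(cohort)
cohort_spec <- function(n_subjects = 20000,
                        female_fraction = 0.86,
                        healthy_fraction = 0.75,
                        insulin_healthy_logmean_f = log(5.8),
                        insulin_healthy_logsd_f = 0.42,
                        insulin_healthy_logmean_m = log(5.6),
                        insulin_healthy_logsd_m = 0.42,
                        pathological_components = list(
                          c(weight = 0.25, logmean = log(14.5), logsd = 0.45)
                        ),
                        glucose_healthy_mean = 89, glucose_healthy_sd = 6,
                        bmi_healthy_mean = 22.8, bmi_healthy_sd = 2.6,
                        a1c_healthy_mean = 5.3, a1c_healthy_sd = 0.25,
                        tg_healthy_logmean = log(75), tg_healthy_logsd = 0.35,
                        hdl_healthy_mean_f = 62, hdl_healthy_sd_f = 10,
                        hdl_healthy_mean_m = 52, hdl_healthy_sd_m = 8,
                        pathology_shift_multipliers = c(
                          glucose = 1.25, bmi = 1.25, a1c = 1.13,
                          tg = 1.9, hdl = 0.85
                        ),
                        medication_prob_given_pathology = 0.5,
                        medication_prob_given_health = 0.05,
                        glucose_insulin_rho = 0.3,
                        age_range = c(20, 60),
                        seed = 1L) {
  spec <- list(
    n_subjects = as.integer(n_subjects),
    female_fraction = female_fraction,
    healthy_fraction = healthy_fraction,
    insulin_healthy_logmean_f = insulin_healthy_logmean_f,
    insulin_healthy_logsd_f = insulin_healthy_logsd_f,
    insulin_healthy_logmean_m = insulin_healthy_logmean_m,
    insulin_healthy_logsd_m = insulin_healthy_logsd_m,
    pathological_components = pathological_components,
    glucose_healthy_mean = glucose_healthy_mean,
    glucose_healthy_sd = glucose_healthy_sd,
    bmi_healthy_mean = bmi_healthy_mean, bmi_healthy_sd = bmi_healthy_sd,
    a1c_healthy_mean = a1c_healthy_mean, a1c_healthy_sd = a1c_healthy_sd,
    tg_healthy_logmean = tg_healthy_logmean,
    tg_healthy_logsd = tg_healthy_logsd,
    hdl_healthy_mean_f = hdl_healthy_mean_f,
    hdl_healthy_sd_f = hdl_healthy_sd_f,
    hdl_healthy_mean_m = hdl_healthy_mean_m,
    hdl_healthy_sd_m = hdl_healthy_sd_m,
    pathology_shift_multipliers = pathology_shift_multipliers,
    medication_prob_given_pathology = medication_prob_given_pathology,
    medication_prob_given_health = medication_prob_given_health,
    glucose_insulin_rho = glucose_insulin_rho,
    age_range = age_range,
    seed = as.integer(seed)
  )
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
}

validate_cohort_spec <- function(spec) {
  stop_field <- function(field, msg) {
    stop(sprintf("invalid cohort_spec: field '%s' %s", field, msg), call. = FALSE)
  }
  if (!is.numeric(spec$n_subjects) || spec$n_subjects < 1) {
    stop_field("n_subjects", "must be a positive count")
  }
  for (f in c("female_fraction", "healthy_fraction",
              "medication_prob_given_pathology",
              "medication_prob_given_health")) {
    v <- spec[[f]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1) {
      stop_field(f, "must be a proportion in [0, 1]")
    }
  }
  for (f in c("insulin_healthy_logsd_f", "insulin_healthy_logsd_m",
              "glucose_healthy_sd", "bmi_healthy_sd", "a1c_healthy_sd",
              "tg_healthy_logsd", "hdl_healthy_sd_f", "hdl_healthy_sd_m")) {
    if (!is.numeric(spec[[f]]) || spec[[f]] < 0) {
      stop_field(f, "must be a non-negative scale parameter")
    }
  }
  if (abs(spec$glucose_insulin_rho) >= 1) {
    stop_field("glucose_insulin_rho", "must lie in (-1, 1)")
  }
  ar <- spec$age_range
  if (length(ar) != 2 || ar[1] > ar[2] || ar[1] < 20 || ar[2] > 60) {
    stop_field("age_range", "must be an ordered pair within [20, 60]")
  }
  comps <- spec$pathological_components
  if (length(comps) > 0) {
    for (cc in comps) {
      if (!all(c("weight", "logmean", "logsd") %in% names(cc))) {
        stop_field("pathological_components",
                   "entries need weight, logmean, logsd")
      }
      if (cc[["weight"]] < 0 || cc[["logsd"]] < 0) {
        stop_field("pathological_components",
                   "weights and logsds must be non-negative")
      }
    }
    # normalize healthy + pathological weights to 1
    wpath <- vapply(comps, function(cc) cc[["weight"]], numeric(1))
    total <- spec$healthy_fraction + sum(wpath)
    if (total <= 0) stop_field("healthy_fraction", "total weight must be > 0")
    spec$healthy_fraction <- spec$healthy_fraction / total
    spec$pathological_components <- lapply(comps, function(cc) {
      cc[["weight"]] <- cc[["weight"]] / total
      cc
    })
  } else {
    spec$healthy_fraction <- 1
  }
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort spec:", x$n_subjects, "subjects,",
      sprintf("%.0f%% female,", 100 * x$female_fraction),
      sprintf("%.0f%% healthy,", 100 * x$healthy_fraction),
      length(x$pathological_components), "pathological component(s)\n")
  cat("  healthy insulin (F): lognormal(", round(x$insulin_healthy_logmean_f, 3),
      ",", x$insulin_healthy_logsd_f, "); ages", x$age_range[1], "-",
      x$age_range[2], "; seed", x$seed, "\n")
  invisible(x)
}

# positive truncated-normal draw: resample any non-positive values
rnorm_pos <- function(n, mean, sd, lower = .Machine$double.eps) {
  x <- rnorm(n, mean, sd)
  bad <- which(x <= lower)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lower]
  }
  x
}

#' Generate a synthetic laboratory cohort
#'
#' Draws one visit per subject from the generative model in a
#' [cohort_spec()]. Healthy subjects get lognormal insulin (per sex) with a
#' latent-factor correlation to glucose; pathological subjects draw insulin
#' from the spec's contamination components and have their other analytes
#' multiplied by the pathology shift multipliers, which pushes many (not
#' all) of them across the exclusion thresholds — the premise of the
#' indirect method is precisely that filtering is imperfect. Medication
#' flags are drawn conditionally on health status. All analyte values are
#' strictly positive (non-positive draws are resampled).
#'
#' The column `is_healthy_truth` is a generator-only label for scoring;
#' no estimation function reads it.
#'
#' @param spec a [cohort_spec()].
#' @return A data.frame with one row per subject: `subject_id`, `sex`
#'   (`"F"`/`"M"`), `age`, `weight` (kg), `height` (m), `insulin` (uU/mL),
#'   `glucose` (mg/dL), `a1c` (%), `hdl` (mg/dL), `tg` (mg/dL),
#'   `medications` (comma-joined classes or `""`), `yearly_exam_count`,
#'   `is_healthy_truth`.
#' @export
generate_cohort <- function(spec) {
  spec <- validate_cohort_spec(spec)
  n <- spec$n_subjects
  set.seed(spec$seed)

  n_f <- round(n * spec$female_fraction)
  sex <- c(rep("F", n_f), rep("M", n - n_f))

  # component assignment: 0 = healthy, 1..K = pathological
  comps <- spec$pathological_components
  K <- length(comps)
  wts <- c(spec$healthy_fraction,
           vapply(comps, function(cc) cc[["weight"]], numeric(1)))
  comp <- sample.int(K + 1, n, replace = TRUE, prob = wts) - 1L
  healthy <- comp == 0L

  age <- runif(n, spec$age_range[1], spec$age_range[2])

  # insulin: healthy per-sex lognormal; pathological from contamination comps
  lmu <- ifelse(sex == "F", spec$insulin_healthy_logmean_f,
                spec$insulin_healthy_logmean_m)
  lsd <- ifelse(sex == "F", spec$insulin_healthy_logsd_f,
                spec$insulin_healthy_logsd_m)
  # shared latent factor drives the healthy glucose-insulin correlation
  rho <- spec$glucose_insulin_rho
  z_shared <- rnorm(n)
  z_ins <- rho * z_shared + sqrt(1 - rho^2) * rnorm(n)
  z_glu <- rho * z_shared + sqrt(1 - rho^2) * rnorm(n)
  insulin <- exp(lmu + lsd * z_ins)
  if (K > 0) {
    for (j in seq_len(K)) {
      sel <- comp == j
      if (any(sel)) {
        insulin[sel] <- rlnorm(sum(sel), comps[[j]][["logmean"]],
                               comps[[j]][["logsd"]])
      }
    }
  }

  mult <- spec$pathology_shift_multipliers
  m_of <- function(nm) if (nm %in% names(mult)) mult[[nm]] else 1
  shift <- function(x, nm) ifelse(healthy, x, x * m_of(nm))

  glucose <- spec$glucose_healthy_mean + spec$glucose_healthy_sd * z_glu
  glucose <- shift(glucose, "glucose")
  glucose[glucose <= 0] <- rnorm_pos(sum(glucose <= 0),
                                     spec$glucose_healthy_mean,
                                     spec$glucose_healthy_sd)
  bmi <- shift(rnorm_pos(n, spec$bmi_healthy_mean, spec$bmi_healthy_sd), "bmi")
  a1c <- shift(rnorm_pos(n, spec$a1c_healthy_mean, spec$a1c_healthy_sd), "a1c")
  tg <- shift(rlnorm(n, spec$tg_healthy_logmean, spec$tg_healthy_logsd), "tg")
  hdl_mu <- ifelse(sex == "F", spec$hdl_healthy_mean_f, spec$hdl_healthy_mean_m)
  hdl_sd <- ifelse(sex == "F", spec$hdl_healthy_sd_f, spec$hdl_healthy_sd_m)
  hdl <- shift(rnorm_pos(n, hdl_mu, hdl_sd), "hdl")

  height <- pmin(pmax(
    rnorm(n, ifelse(sex == "F", 1.61, 1.75), ifelse(sex == "F", 0.06, 0.07)),
    1.25), 2.15)
  weight <- bmi * height^2

  med_p <- ifelse(healthy, spec$medication_prob_given_health,
                  spec$medication_prob_given_pathology)
  has_med <- runif(n) < med_p
  med_classes <- c("antidiabetic", "lipid_lowering", "antihypertensive")
  medications <- character(n)
  if (any(has_med)) {
    medications[has_med] <- vapply(which(has_med), function(i) {
      k <- sample.int(3, 1)
      paste(sort(sample(med_classes, k)), collapse = ",")
    }, character(1))
  }

  exam_probs_h <- c(0.70, 0.25, 0.04, 0.01)
  exam_probs_p <- c(0.45, 0.30, 0.15, 0.10)
  yearly <- integer(n)
  yearly[healthy] <- sample(1:4, sum(healthy), TRUE, exam_probs_h)
  if (any(!healthy)) yearly[!healthy] <- sample(1:4, sum(!healthy), TRUE,
                                                exam_probs_p)

  data.frame(
    subject_id = sprintf("S%06d", seq_len(n)),
    sex = sex,
    age = age,
    weight = weight,
    height = height,
    insulin = insulin,
    glucose = glucose,
    a1c = a1c,
    hdl = hdl,
    tg = tg,
    medications = medications,
    yearly_exam_count = yearly,
    is_healthy_truth = healthy,
    stringsAsFactors = FALSE
  )
}

#' Closed-form quantiles of the healthy insulin component
#'
#' The healthy fasting-insulin component is lognormal per sex, so its
#' quantiles are `exp(logmean + qnorm(p) * logsd)`. For `sex = "all"` the
#' healthy population is the female/male mixture weighted by
#' `female_fraction`; its quantiles are found by numerically inverting the
#' mixture CDF. These are the ground truth that recovery tests score
#' [run_indirect_ri()] against.
#'
#' @param spec a [cohort_spec()].
#' @param sex `"F"`, `"M"` or `"all"`.
#' @param probs probabilities in (0, 1).
#' @return Quantiles in uU/mL.
#' @export
#' @examples
#' true_healthy_quantiles(cohort_spec(), "F", c(0.025, 0.5, 0.975))
true_healthy_quantiles <- function(spec, sex = c("all", "F", "M"),
                                   probs = c(0.025, 0.975)) {
  spec <- validate_cohort_spec(spec)
  sex <- match.arg(sex)
  stopifnot(all(probs > 0 & probs < 1))
  if (sex == "F") {
    return(exp(spec$insulin_healthy_logmean_f +
                 qnorm(probs) * spec$insulin_healthy_logsd_f))
  }
  if (sex == "M") {
    return(exp(spec$insulin_healthy_logmean_m +
                 qnorm(probs) * spec$insulin_healthy_logsd_m))
  }
  wf <- spec$female_fraction
  cdf <- function(x) {
    wf * pnorm(log(x), spec$insulin_healthy_logmean_f,
               spec$insulin_healthy_logsd_f) +
      (1 - wf) * pnorm(log(x), spec$insulin_healthy_logmean_m,
                       spec$insulin_healthy_logsd_m)
  }
  lo <- exp(min(spec$insulin_healthy_logmean_f, spec$insulin_healthy_logmean_m) -
              10 * max(spec$insulin_healthy_logsd_f, spec$insulin_healthy_logsd_m,
                       0.1))
  hi <- exp(max(spec$insulin_healthy_logmean_f, spec$insulin_healthy_logmean_m) +
              10 * max(spec$insulin_healthy_logsd_f, spec$insulin_healthy_logsd_m,
                       0.1))
  vapply(probs, function(p) {
    uniroot(function(x) cdf(x) - p, c(lo, hi), tol = 1e-12)$root
  }, numeric(1))
}

#' Write / read a cohort as CSV
#'
#' The CSV dialect is one row per subject-visit with the column set
#' documented in [generate_cohort()]. `write_cohort_csv()` also drops a
#' small JSON provenance file (`<path>.provenance.json`) recording the seed
#' and generator parameters when the cohort came from a [cohort_spec()].
#'
#' @param cohort a cohort data.frame.
#' @param path output CSV path.
#' @param spec optional [cohort_spec()] recorded in the provenance file.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path, spec = NULL) {
  write.csv(cohort, path, row.names = FALSE)
  if (!is.null(spec)) {
    prov <- unclass(spec)
    jsonlite::write_json(prov, paste0(path, ".provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if ("medications" %in% names(df)) {
    df$medications[is.na(df$medications)] <- ""
  }
  df
}
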
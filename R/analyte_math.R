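#' Unit conversion conventions
#'
#' Two conventions for insulin circulate in the clinical literature: the
#' WHO/ADA factor 1 uU/mL = 6.00 pmol/L, and a legacy reciprocal rule
#' "multiply pmol/L by 0.166 to get uU/mL", i.e. uU/mL -> pmol/L divides by
#' 0.166 (= x6.024). The two differ by the fixed ratio 6.00 x 0.166 = 0.996,
#' which is why tables converted with one convention are off by ~0.4% from
#' the other. Glucose, triglycerides and HDL-c use the manufacturer factors
#' 18.02, 88.5 and 38.67 mg/dL per mmol/L.
#'
#' @param insulin_convention `"who"` (x 6.00) or `"legacy_reciprocal"`
#'   (/ 0.166).
#' @return An object of class `unit_convention` with fields
#'   `insulin_uU_to_pmol_factor`, `glucose_mg_per_mmol`, `tg_mg_per_mmol`,
#'   `hdl_mg_per_mmol` and `name`.
#' @export
#' @examples
#' convert_analyte(6.61, "insulin", "to_si", unit_convention("legacy_reciprocal"))
unit_convention <- function(insulin_convention = c("who", "legacy_reciprocal")) {
  insulin_convention <- match.arg(insulin_convention)
  structure(list(
    name = insulin_convention,
    insulin_uU_to_pmol_factor = switch(insulin_convention,
                                       who = 6.00,
                                       legacy_reciprocal = 1 / 0.166),
    glucose_mg_per_mmol = 18.02,
    tg_mg_per_mmol = 88.5,
    hdl_mg_per_mmol = 38.67
  ), class = "unit_convention")
}

#' HOMA-IR index
#'
#' Homeostasis model assessment of insulin resistance:
#' `glucose (mmol/L) * insulin (uU/mL) / 22.5`. Note the glucose must
#' already be in mmol/L; use [add_homa()] for mg/dL cohort columns.
#'
#' @param glucose_mmol fasting glucose, mmol/L, > 0.
#' @param insulin_uU fasting insulin, uU/mL, > 0.
#' @return The dimensionless HOMA-IR index.
#' @export
#' @examples
#' homa_ir(4.5, 10) # 2.0
homa_ir <- function(glucose_mmol, insulin_uU) {
  if (any(!is.finite(glucose_mmol)) || any(!is.finite(insulin_uU)) ||
      any(glucose_mmol <= 0) || any(insulin_uU <= 0)) {
    stop("homa_ir: glucose and insulin must be finite and positive",
         call. = FALSE)
  }
  glucose_mmol * insulin_uU / 22.5
}

#' Convert analyte values between conventional and SI units
#'
#' Multiplicative conversion: `to_si` maps uU/mL -> pmol/L for insulin and
#' mg/dL -> mmol/L for glucose, triglycerides and HDL-c; `from_si` is the
#' exact reciprocal, so a round trip returns the input to floating-point
#' accuracy.
#'
#' @param value analyte value(s), >= 0.
#' @param analyte one of `"insulin"`, `"glucose"`, `"tg"`, `"hdl"`.
#' @param direction `"to_si"` or `"from_si"`.
#' @param convention a [unit_convention()].
#' @return Converted value(s).
#' @export
convert_analyte <- function(value, analyte = c("insulin", "glucose", "tg", "hdl"),
                            direction = c("to_si", "from_si"),
                            convention = unit_convention()) {
  analyte <- match.arg(analyte)
  direction <- match.arg(direction)
  if (any(value < 0, na.rm = TRUE)) {
    stop("convert_analyte: values must be non-negative", call. = FALSE)
  }
  factor <- switch(analyte,
    insulin = convention$insulin_uU_to_pmol_factor,
    glucose = 1 / convention$glucose_mg_per_mmol,
    tg = 1 / convention$tg_mg_per_mmol,
    hdl = 1 / convention$hdl_mg_per_mmol
  )
  if (direction == "to_si") value * factor else value / factor
}

#' Append a HOMA-IR column to a cohort
#'
#' Converts the mg/dL `glucose` column to mmol/L with the convention's
#' factor, then applies [homa_ir()] row-wise. Row order is preserved.
#'
#' @param records cohort data.frame with `glucose` (mg/dL) and `insulin`
#'   (uU/mL) columns.
#' @param convention a [unit_convention()].
#' @return `records` with a `homa_ir` column appended.
#' @export
add_homa <- function(records, convention = unit_convention()) {
  if (nrow(records) == 0) {
    records$homa_ir <- numeric(0)
    return(records)
  }
  bad <- !is.finite(records$glucose) | records$glucose <= 0 |
    !is.finite(records$insulin) | records$insulin <= 0
  if (any(bad)) {
    ids <- if ("subject_id" %in% names(records)) {
      paste(head(records$subject_id[bad], 5), collapse = ", ")
    } else {
      paste(head(which(bad), 5), collapse = ", ")
    }
    stop("add_homa: non-positive glucose/insulin for record(s): ", ids,
         call. = FALSE)
  }
  records$homa_ir <- homa_ir(records$glucose / convention$glucose_mg_per_mmol,
                             records$insulin)
  records
}
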
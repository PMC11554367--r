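#' Published benchmark values from the source reference-interval study
#'
#' The printed values of the large Rio de Janeiro laboratory-database study
#' this workflow replicates, used as arithmetic inputs (unit-conversion
#' checks, cohort-composition percentages) — not as assertions about any
#' synthetic cohort. All insulin values are uU/mL unless noted.
#'
#' @return A list with:
#' \describe{
#'   \item{counts}{screened/retained cohort sizes and female counts.}
#'   \item{proposed_ri_insulin}{the overall proposed insulin RI bounds.}
#'   \item{proposed_ri_insulin_pmol}{their printed pmol/L counterparts.}
#'   \item{proposed_ri_homa}{the overall HOMA-IR RI bounds.}
#'   \item{table1_medians}{female medians: insulin (uU/mL and pmol/L),
#'     glucose (mg/dL and mmol/L), tg (mg/dL and mmol/L).}
#' }
#' @export
study_benchmarks <- function() {
  list(
    counts = list(
      n_initial = 146497, n_initial_female = 102380,
      n_final = 21684, n_final_female = 18576, n_final_male = 3108
    ),
    proposed_ri_insulin = c(lower = 2.52, upper = 13.14),
    proposed_ri_insulin_pmol = c(lower = 15.1, upper = 78.8),
    proposed_ri_homa = c(lower = 0.39, upper = 2.86),
    table1_medians = list(
      insulin_uU = 6.61, insulin_pmol = 39.8,
      glucose_mg = 89, glucose_mmol = 4.9,
      tg_mg = 73, tg_mmol = 0.8
    )
  )
}
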
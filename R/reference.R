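#' Published sensitivity benchmark for the hospital NSI study
#'
#' The published hospital study behind this package reports, for each of
#' the 11 predictors, the posterior percentage of `"NSIs = no"` under the
#' predictor's worst and best states, a sensitivity column, and the mutual
#' information with the outcome (bits, with percent of outcome entropy in
#' parentheses).  The raw hospital data are not public, so these printed
#' rows serve as the package's arithmetic benchmark: [sensitivity_index()]
#' must reproduce the sensitivity column from the two posterior columns,
#' and the best-state posteriors imply the published intervention NSI
#' rates (e.g. `100 - 79.5 = 20.5`).
#'
#' @return Data frame with columns `predictor`, `group`, `worst_pct`,
#'   `best_pct`, `sensitivity_pct`, `mi_bits`, `mi_pct`.
#' @export
nsi_reference_sensitivity <- function() {
  pre <- "Preconditions for unsafe acts"
  sup <- "Unsafe supervision"
  org <- "Organizational influences"
  data.frame(
    predictor = c("safety_motivation", "fatigue", "teamwork",
                  "physical_environment", "supervisor_attitude",
                  "safety_training", "working_hours", "night_shifts",
                  "staffing", "management_commitment", "safe_procedures"),
    group = c(pre, pre, pre, pre, sup, sup, sup, sup, org, org, org),
    worst_pct = c(62.8, 65.3, 67.2, 66.7, 59.6, 66.5, 63.8, 64.9,
                  65.2, 66.0, 71.9),
    best_pct = c(79.5, 78.6, 75.3, 79.4, 77.7, 74.8, 78.8, 75.7,
                 76.0, 75.8, 72.2),
    sensitivity_pct = c(26.6, 20.4, 12.1, 19.0, 30.4, 12.5, 23.5, 16.6,
                        16.6, 14.8, 0.4),
    mi_bits = c(0.019, 0.016, 0.005, 0.017, 0.019, 0.004, 0.013, 0.007,
                0.008, 0.007, 0.000),
    mi_pct = c(2.3, 1.8, 0.6, 2.0, 2.3, 0.5, 1.5, 0.9, 1.0, 0.8, 0.0),
    stringsAsFactors = FALSE)
}
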
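#' Published MPN-NOS validation score table
#'
#' The per-class classification scores, model predictions and reference
#' classifications reported for the 13 MPN-NOS validation patients of the
#' source cohort. `histology` is the pathologists' morphology call at
#' biopsy (overlap tokens allowed); `followup` the clinical diagnosis at
#' follow-up (`UNCHANGED*` / `NA` where none was reached). Used to
#' reproduce the argmax/tie-rule prediction column and the concordance
#' rates.
#'
#' @return tibble with columns `patient_id`, `score_prePMF`, `score_PV`,
#'   `score_ET`, `published_prediction`, `histology`, `followup`.
#' @export
nos_validation_scores <- function() {
  tibble::tribble(
    ~patient_id, ~score_prePMF, ~score_PV, ~score_ET, ~published_prediction, ~histology,          ~followup,
    "BMB 103",   0.13,          0.76,      0.11,      "PV",                  "pre-PMF-/PV-LIKE",  "PV",
    "BMB 114",   0.30,          0.35,      0.35,      "ET",                  "pre-PMF-/ET LIKE",  "UNCHANGED (>LDH)",
    "BMB 15",    0.25,          0.29,      0.47,      "ET",                  "ET-LIKE",           "PV",
    "BMB 2",     0.18,          0.65,      0.16,      "PV",                  "pre-PMF-/ET-LIKE",  "ET",
    "BMB 24",    0.25,          0.03,      0.72,      "ET",                  "pre-PMF-/ET-LIKE",  "UNCHANGED (>LDH)",
    "BMB 36",    0.10,          0.82,      0.08,      "PV",                  "pre-PMF-/PV-LIKE",  "UNCHANGED",
    "BMB 40",    0.18,          0.62,      0.20,      "PV",                  "PV-LIKE",           NA,
    "BMB 41",    0.18,          0.58,      0.24,      "PV",                  "pre-PMF-/ET-LIKE",  NA,
    "BMB 63",    0.12,          0.76,      0.12,      "PV",                  "PV-LIKE",           "PV",
    "BMB 79",    0.27,          0.24,      0.49,      "ET",                  "ET-LIKE",           "ET",
    "BMB 93",    0.22,          0.15,      0.63,      "ET",                  "ET-LIKE",           "PV",
    "BMB 1643",  0.22,          0.04,      0.74,      "ET",                  "ET-LIKE",           "PMF",
    "BMB 1644",  0.22,          0.03,      0.75,      "ET",                  "ET-LIKE",           "ET"
  )
}
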
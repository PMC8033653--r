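# Registries: the 34-variable physiological panel with cohort-scale summary
# statistics and plausibility bounds, and the 30 Elixhauser comorbidity
# categories with van Walraven index weights.

#' Physiological variable registry
#'
#' Returns the registry of the 34 candidate physiological variables used
#' throughout the pipeline: short machine names, display labels with units,
#' default cohort-scale mean and standard deviation (used by the synthetic
#' cohort generator), and measurable-range plausibility bounds in natural
#' units (used for outlier filtering).
#'
#' @return A data.frame with columns `variable`, `label`, `mean`, `sd`,
#'   `lo`, `hi`; one row per variable, fixed order.
#' @export
#' @examples
#' reg <- variable_registry()
#' reg[reg$variable == "heart_rate", c("mean", "sd")]
variable_registry <- function() {
  df <- data.frame(
    variable = c(
      "heart_rate", "resp_rate", "gcs_motor", "map", "dbp", "sbp",
      "urine_output", "temperature", "spo2", "fio2", "pao2", "pf_ratio",
      "wbc", "hemoglobin", "hematocrit", "ph", "magnesium",
      "platelets", "ptt", "inr", "bun", "creatinine", "bilirubin_total",
      "bilirubin_direct", "ast", "base_excess", "glucose", "chloride",
      "bicarbonate", "lactate", "albumin", "co2", "potassium", "sodium"
    ),
    label = c(
      "Heart rate (bpm)", "Respiration rate (insp/min)",
      "Glasgow coma scale motor", "Mean arterial blood pressure (mmHg)",
      "Diastolic blood pressure (mmHg)", "Systolic blood pressure (mmHg)",
      "Urine output (mL)", "Temperature (Celsius)",
      "Blood oxygen saturation (%)", "Fraction of inspired O2 (%)",
      "Partial pressure of oxygen (mmHg)", "PaO2/FiO2 ratio",
      "White blood cell count (K/uL)", "Hemoglobin (g/dl)",
      "Hematocrit (%)", "Ph (unit)", "Magnesium (mg/dL)",
      "Platelet count (K/uL)", "Partial prothrombin time (sec)",
      "International normalized ratio", "Blood urea nitrogen (mg/dL)",
      "Blood serum creatinine (mg/dL)", "Blood total bilirubin (mg/dL)",
      "Blood direct bilirubin (mg/dL)", "Aspartate aminotransferase (IU/L)",
      "Base excess (mEq/L)", "Glucose (mg/dL)", "Chloride (mEq/L)",
      "Bicarbonate (mEq/L)", "Lactate (mmol/L)", "Blood albumin (g/dL)",
      "Carbon dioxide (mEq/L)", "Blood serum potassium (mEq/L)",
      "Blood sodium (mEq/L)"
    ),
    mean = c(
      88.4, 20.4, 5.1, 79.2, 61.7, 121.6, 120.7, 37.1, 97.0, 47.5, 99.4,
      208.2, 12.1, 10.0, 29.6, 7.4, 2.1,
      215.3, 40.4, 1.5, 32.8, 1.5, 3.0, 4.4, 61.7, -0.1, 136.7, 105.2,
      24.7, 2.3, 2.8, 26.0, 4.1, 139.3
    ),
    sd = c(
      19.0, 6.2, 1.5, 18.2, 14.7, 23.7, 114.6, 0.9, 3.2, 14.8, 34.0,
      110.5, 6.9, 1.8, 5.2, 0.1, 0.4,
      147.6, 17.1, 0.6, 25.8, 1.3, 4.3, 5.4, 43.1, 5.6, 51.2, 6.9,
      5.4, 1.6, 0.6, 6.3, 0.7, 5.8
    ),
    lo = c(
      0, 0, 1, 0, 0, 0, 0, 25, 0, 21, 0, 0, 0, 0, 0, 6.5, 0,
      0, 0, 0, 0, 0, 0, 0, 0, -40, 0, 50, 0, 0, 0, 0, 0, 90
    ),
    hi = c(
      300, 120, 6, 250, 200, 300, 2000, 45, 100, 100, 700, 700, 200, 25,
      75, 8, 10,
      2000, 200, 20, 300, 40, 80, 80, 10000, 40, 2000, 160, 60, 40, 10,
      80, 15, 200
    ),
    stringsAsFactors = FALSE
  )
  df
}

#' Measurable-range table
#'
#' Plausibility bounds per variable in natural units; records outside the
#' closed interval `[lo, hi]` are treated as recording artifacts (for
#' example, a respiratory rate of 2,355,555 breaths per minute) and removed
#' during preprocessing.
#'
#' @return data.frame with columns `variable`, `lo`, `hi`.
#' @export
measurable_ranges <- function() {
  variable_registry()[, c("variable", "lo", "hi")]
}

#' Elixhauser comorbidity registry
#'
#' The 30 Elixhauser comorbidity categories in fixed registry order, with
#' van Walraven index weights (the default weighting for the comorbidity
#' index used as a mortality benchmark).
#'
#' @return data.frame with columns `category` and `weight`.
#' @export
elixhauser_registry <- function() {
  data.frame(
    category = c(
      "congestive_heart_failure", "cardiac_arrhythmias", "valvular_disease",
      "pulmonary_circulation", "peripheral_vascular", "hypertension",
      "paralysis", "neurologic_disease", "chronic_pulmonary",
      "diabetes_uncomplicated", "diabetes_complicated", "hypothyroidism",
      "renal_failure", "liver_disease", "peptic_ulcer", "aids_hiv",
      "lymphoma", "metastatic_cancer", "solid_tumor", "rheumatoid_arthritis",
      "coagulopathy", "obesity", "weight_loss", "fluid_electrolyte",
      "blood_loss_anemia", "deficiency_anemias", "alcohol_abuse",
      "drug_abuse", "psychoses", "depression"
    ),
    weight = c(
      7, 5, -1, 4, 2, 0, 7, 6, 3, 0, 0, 0, 5, 11, 0, 0, 9, 12, 4, 0,
      3, -4, 6, 5, -2, -2, 0, -7, 0, -3
    ),
    stringsAsFactors = FALSE
  )
}

# number of 6-h windows over the 72-h horizon at a given interval
n_windows <- function(interval = 6, horizon = 72) {
  stopifnot(horizon %% interval == 0)
  as.integer(horizon / interval)
}
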
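#' Canonical harmonized factor levels
#'
#' The level vocabulary every module shares: harmonization emits these
#' levels, weight tables are validated against them, and the synthetic
#' generator draws from them. Levels are ordered; for graded factors the
#' order runs from the first printed level to the last.
#'
#' @return named list of character vectors (factor -> ordered levels).
#' @export
factor_levels <- function() {
  list(
    sex                  = c("female", "male"),
    education            = c("low", "medium", "high"),
    alcohol              = c("none", "low_moderate", "high"),
    apoe4                = c("non_carrier", "carrier"),
    bmi                  = c("underweight", "normal", "overweight", "obese"),
    cognitive_activity   = c("low", "medium", "high"),
    heart_disease        = c("no", "yes"),
    depression           = c("no", "yes"),
    diabetes             = c("no", "yes"),
    fish_intake          = c("0-0.25", "0.26-2", "2.1-4", ">4.1"),
    mediterranean_diet   = c("yes", "no"),
    hearing              = c("no", "yes"),
    hypercholesterolemia = c("no", "yes"),
    hypertension         = c("no", "yes"),
    physical_activity    = c("low", "medium", "high"),
    physical_activity_caide = c("active", "inactive"),
    tbi                  = c("no", "yes"),
    sleep_disturbance    = c("no", "yes"),
    smoking              = c("never", "former", "current"),
    social_activity      = c("lowest", "low_medium", "medium_high", "highest"),
    lonely               = c("no", "yes"),
    stroke               = c("no", "yes")
  )
}

#' Names of the five risk indices
#' @return character vector of index identifiers.
#' @export
index_names <- function() {
  c("ANU-ADRI", "CAIDE", "CogDrisk", "LIBRA", "LIBRA2")
}

# Factors whose categories are cohort-relative composites rather than
# prevalence-planted categories.
composite_factors <- function() c("cognitive_activity", "social_activity")

# ICD-10 three-digit code sets used as registry fallback per factor.
registry_code_sets <- function() {
  list(
    depression    = c("F32", "F33"),
    diabetes      = paste0("E", 10:14),
    hypertension  = c("I10", "I15"),
    heart_disease = c("I11", paste0("I", 20:25), "I50", "I51"),
    stroke        = paste0("I", 60:69),
    tbi           = c("S06", "S07", "S09")
  )
}
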
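cohort_dictionary <- function(data) {
  units <- c(
    baseline_age = "years", follow_up_age = "years", height = "m",
    weight = "kg", systolic_bp_2nd = "mmHg", systolic_bp_3rd = "mmHg",
    total_cholesterol = "mmol/L", non_fasting_glucose = "mmol/L",
    hads_depression = "score 0-21", alcohol_units_per_week = "units/week",
    mvpa_minutes_per_week = "min/week", mvpa_sessions_per_week = "sessions/week",
    fish_frequency = "band 1-4", fruit_points = "points 1-4",
    vegetable_points = "points 1-4", apoe_e4_count = "alleles 0-2"
  )
  coding <- list(
    sex = c("female", "male"),
    education = factor_levels()$education,
    smoking = factor_levels()$smoking,
    outcome = c("no_cognitive_impairment", "aMCI", "naMCI",
                "dementia_AD", "dementia_other")
  )
  lapply(stats::setNames(names(data), names(data)), function(col) {
    x <- data[[col]]
    entry <- list(
      column = col,
      type = if (is.logical(x)) "boolean" else if (is.numeric(x)) "numeric"
             else "categorical",
      missing_sentinel = "empty field"
    )
    if (col %in% names(units)) entry$units <- unname(units[col])
    if (col %in% names(coding)) entry$coding <- coding[[col]]
    entry
  })
}

#' Write a cohort to CSV with a machine-readable data dictionary
#'
#' One row per participant; missing values are empty fields. The dictionary
#' (JSON) records column name, type, units and coding where applicable.
#'
#' @param data raw cohort tibble (e.g. from [generate_cohort()]).
#' @param path CSV output path.
#' @param dictionary_path JSON dictionary path (default: `path` with a
#'   `_dictionary.json` suffix).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path,
                         dictionary_path = sub("\\.csv$", "", path)) {
  if (!grepl("_dictionary\\.json$", dictionary_path)) {
    dictionary_path <- paste0(dictionary_path, "_dictionary.json")
  }
  utils::write.csv(data, path, row.names = FALSE, na = "")
  jsonlite::write_json(unname(cohort_dictionary(data)), dictionary_path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a cohort CSV written by [write_cohort()]
#'
#' Empty fields become `NA`; boolean columns are restored from the
#' dictionary when present next to the CSV.
#'
#' @param path CSV path.
#' @param dictionary_path JSON dictionary path (default: located next to
#'   the CSV; plain CSVs without a dictionary are read as-is).
#' @return tibble of raw records.
#' @export
read_cohort <- function(path,
                        dictionary_path = paste0(sub("\\.csv$", "", path),
                                                 "_dictionary.json")) {
  out <- as_tibble(utils::read.csv(path, na.strings = ""))
  if (file.exists(dictionary_path)) {
    dict <- jsonlite::read_json(dictionary_path)
    for (entry in dict) {
      col <- entry$column
      if (identical(entry$type, "boolean") && col %in% names(out)) {
        out[[col]] <- as.logical(out[[col]])
      }
    }
  }
  out
}
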
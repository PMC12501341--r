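#' Harmonization configuration
#'
#' @param alcohol_boundary where exactly 14 units/week falls. The printed
#'   bands ("1-14" and ">=14") overlap at 14; the default assigns 14 to
#'   `"high"` (the more specific risk condition) and such boundary cases are
#'   counted in the harmonization log.
#' @param education_bands `"table"` (default): <8 / 8-11 / >11 years, the
#'   banding that carries the index weights; `"text"`: <8 / 8-12 / >12.
#' @param registry_window inclusive years within which registry diagnoses
#'   are accepted.
#' @return a config list used by [harmonize_cohort()].
#' @export
harmonize_config <- function(alcohol_boundary = c("high", "low_moderate"),
                             education_bands = c("table", "text"),
                             registry_window = c(2007, 2009)) {
  list(
    alcohol_boundary = match.arg(alcohol_boundary),
    education_bands = match.arg(education_bands),
    registry_window = registry_window
  )
}

#' Categorize body mass index
#'
#' BMI = weight / height^2 with the conventional cut points: underweight
#' (<18.5), normal (18.5-24.99), overweight (25-29.99), obese (>=30).
#' Boundaries belong to the upper category (25.0 is overweight, 30.0 obese).
#'
#' @param height height in meters.
#' @param weight weight in kilograms.
#' @return character vector of BMI categories (`NA` for nonpositive or
#'   missing inputs, with a warning).
#' @export
categorize_bmi <- function(height, weight) {
  bad <- (!is.na(height) & height <= 0) | (!is.na(weight) & weight <= 0)
  if (any(bad)) warning("nonpositive height/weight set to missing")
  bmi <- ifelse(bad, NA_real_, weight / height^2)
  cut_level(bmi, c(18.5, 25, 30), factor_levels()$bmi)
}

#' Categorize weekly alcohol intake
#'
#' Levels: none (0 units/week), low/moderate (under 14), high (14 or more;
#' see [harmonize_config()] for the boundary convention).
#'
#' @param units units of alcohol per week.
#' @param config a [harmonize_config()].
#' @return character vector of alcohol categories.
#' @export
categorize_alcohol <- function(units, config = harmonize_config()) {
  bad <- !is.na(units) & units < 0
  if (any(bad)) warning("negative alcohol units set to missing")
  units <- ifelse(bad, NA_real_, units)
  out <- rep(NA_character_, length(units))
  out[units == 0] <- "none"
  out[units > 0 & units < 14] <- "low_moderate"
  out[units >= 14] <- "high"
  if (config$alcohol_boundary == "low_moderate") out[units == 14] <- "low_moderate"
  out
}

cut_level <- function(x, breaks, labels) {
  # breaks are lower bounds of categories 2..k; boundary goes up
  idx <- findInterval(x, breaks) + 1L
  labels[idx]
}

# positive registry match per id for one ICD-10 code set
registry_positive <- function(ids, registry, codes, window) {
  if (is.null(registry) || nrow(registry) == 0) return(rep(FALSE, length(ids)))
  reg <- registry[registry$icd10 %in% codes &
                    registry$year >= window[1] & registry$year <= window[2], ]
  ids %in% reg$id
}

# survey -> earlier wave (positive carry-forward) -> registry (positive only)
resolve_flag <- function(survey, earlier = NULL, registry_pos = NULL) {
  n <- length(survey)
  level <- ifelse(is.na(survey), NA_character_, ifelse(survey, "yes", "no"))
  prov <- ifelse(is.na(survey), NA_character_, "survey")
  if (!is.null(earlier)) {
    take <- is.na(level) & !is.na(earlier) & earlier
    level[take] <- "yes"
    prov[take] <- "earlier_wave"
  }
  conflict <- rep(FALSE, n)
  if (!is.null(registry_pos)) {
    take <- is.na(level) & registry_pos
    level[take] <- "yes"
    prov[take] <- "registry"
    conflict <- !is.na(level) & level == "no" & registry_pos
  }
  list(level = level, prov = prov, conflict = conflict)
}

#' Classify clinical and sensory risk-factor flags
#'
#' Applies the survey-first precedence: a survey-derived value always wins;
#' positive reports from earlier waves are carried forward for hearing and
#' stroke; positive registry diagnoses (three-digit ICD-10, within the
#' configured window) fill remaining gaps for depression, diabetes,
#' hypertension, heart disease, stroke and TBI. Registry codes that
#' contradict a survey-derived "no" are logged, not applied.
#'
#' Rules: depression = HADS depression score >= 8; diabetes = self-report or
#' non-fasting glucose >= 9 mmol/L; hypertension = mean of the 2nd and 3rd
#' systolic readings >= 140 mm Hg (mean of available readings if one is
#' missing); hypercholesterolemia = total cholesterol >= 6.5 mmol/L; sleep
#' disturbance = any of the three insomnia items several times a week;
#' APOE carrier = at least one epsilon-4 allele.
#'
#' @param data raw cohort tibble (see [generate_cohort()] for the schema).
#' @param registry optional long tibble `(id, icd10, year)`.
#' @param config a [harmonize_config()].
#' @return list with `levels` (tibble of factor levels), `prov` (matching
#'   provenance tibble) and `conflicts` (survey/registry disagreements).
#' @export
classify_clinical <- function(data, registry = NULL, config = harmonize_config()) {
  codes <- registry_code_sets()
  win <- config$registry_window
  n <- nrow(data)
  rp <- function(f) registry_positive(data$id, registry, codes[[f]], win)

  depression <- resolve_flag(ge(data$hads_depression, 8), registry_pos = rp("depression"))

  diab_pos <- (data$diabetes_self_report %in% TRUE) |
    (!is.na(data$non_fasting_glucose) & data$non_fasting_glucose >= 9)
  diab_obs <- (!is.na(data$diabetes_self_report)) | (!is.na(data$non_fasting_glucose))
  diabetes <- resolve_flag(ifelse(diab_obs, diab_pos, NA), registry_pos = rp("diabetes"))

  sbp <- rowMeans(cbind(data$systolic_bp_2nd, data$systolic_bp_3rd), na.rm = TRUE)
  sbp[is.nan(sbp)] <- NA
  hypertension <- resolve_flag(ge(sbp, 140), registry_pos = rp("hypertension"))

  hchol <- resolve_flag(ge(data$total_cholesterol, 6.5))

  heart_any <- pmax_flag(data$angina, data$heart_failure,
                         data$myocardial_infarction, data$other_heart_disease)
  heart <- resolve_flag(heart_any, registry_pos = rp("heart_disease"))

  stroke <- resolve_flag(data$stroke_self_report,
                         earlier = data$stroke_earlier_wave,
                         registry_pos = rp("stroke"))
  tbi <- resolve_flag(data$tbi_ever_hospitalized, registry_pos = rp("tbi"))
  hearing <- resolve_flag(data$hearing_loss_survey,
                          earlier = data$hearing_loss_earlier_wave)

  sleep_any <- pmax_flag(data$sleep_onset, data$sleep_maintenance,
                         data$sleep_early_waking)
  sleep <- resolve_flag(sleep_any)

  apoe_lvl <- ifelse(is.na(data$apoe_e4_count), NA_character_,
                     ifelse(data$apoe_e4_count >= 1, "carrier", "non_carrier"))

  levels <- tibble(
    depression = depression$level, diabetes = diabetes$level,
    hypertension = hypertension$level, hypercholesterolemia = hchol$level,
    heart_disease = heart$level, stroke = stroke$level, tbi = tbi$level,
    hearing = hearing$level, sleep_disturbance = sleep$level,
    apoe4 = apoe_lvl
  )
  prov <- tibble(
    depression = depression$prov, diabetes = diabetes$prov,
    hypertension = hypertension$prov, hypercholesterolemia = hchol$prov,
    heart_disease = heart$prov, stroke = stroke$prov, tbi = tbi$prov,
    hearing = hearing$prov, sleep_disturbance = sleep$prov,
    apoe4 = ifelse(is.na(apoe_lvl), NA_character_, "survey")
  )
  conflict_mat <- cbind(
    depression = depression$conflict, diabetes = diabetes$conflict,
    hypertension = hypertension$conflict, heart_disease = heart$conflict,
    stroke = stroke$conflict, tbi = tbi$conflict
  )
  conflicts <- which(conflict_mat, arr.ind = TRUE)
  conflicts <- tibble(
    id = data$id[conflicts[, 1]],
    factor = colnames(conflict_mat)[conflicts[, 2]]
  )
  list(levels = levels, prov = prov, conflicts = conflicts)
}

ge <- function(x, cut) ifelse(is.na(x), NA, x >= cut)

# elementwise any-TRUE over logical vectors; FALSE only if all observed FALSE
pmax_flag <- function(...) {
  m <- cbind(...)
  any_true <- rowSums(m, na.rm = TRUE) > 0
  all_obs <- rowSums(is.na(m)) == 0
  ifelse(any_true, TRUE, ifelse(all_obs, FALSE, NA))
}

#' Categorize activity, smoking and diet variables
#'
#' Physical activity: under 30 MVPA minutes/week is low, 30-149 medium,
#' 150+ high. The CAIDE binary is its own rule: active = at least two
#' sessions a week averaging at least 30 minutes each. Smoking is the
#' three-level survey response. Fish intake maps the four frequency bands;
#' the diet score sums fruit, vegetable and fish points (1-4 each) and is
#' healthy at 10 points or more.
#'
#' @inheritParams classify_clinical
#' @return list with `levels` and `prov` tibbles.
#' @export
categorize_activity <- function(data) {
  minutes <- data$mvpa_minutes_per_week
  sessions <- data$mvpa_sessions_per_week
  pa <- cut_level(minutes, c(30, 150), factor_levels()$physical_activity)
  per_session <- ifelse(!is.na(sessions) & sessions > 0, minutes / sessions, 0)
  caide <- ifelse(is.na(minutes) | is.na(sessions), NA_character_,
                  ifelse(sessions >= 2 & per_session >= 30, "active", "inactive"))

  smoking <- as.character(data$smoking)

  fish <- factor_levels()$fish_intake[data$fish_frequency]
  diet_sum <- data$fruit_points + data$vegetable_points + data$fish_frequency
  med <- ifelse(is.na(diet_sum), NA_character_, ifelse(diet_sum >= 10, "yes", "no"))

  list(
    levels = tibble(physical_activity = pa, physical_activity_caide = caide,
                    smoking = smoking, fish_intake = fish,
                    mediterranean_diet = med),
    prov = tibble(
      physical_activity = prov_if(pa, "survey"),
      physical_activity_caide = prov_if(caide, "derived"),
      smoking = prov_if(smoking, "survey"),
      fish_intake = prov_if(fish, "survey"),
      mediterranean_diet = prov_if(med, "derived")
    )
  )
}

prov_if <- function(level, tag) ifelse(is.na(level), NA_character_, tag)

# midrank-based quantile groups, ties to the lower group
quantile_groups <- function(x, k) {
  p <- rank(x, ties.method = "average", na.last = "keep") / sum(!is.na(x))
  cuts <- seq_len(k - 1) / k
  g <- rep(1L, length(x))
  for (c in cuts) g <- g + (p > c + 1e-12)
  g[is.na(x)] <- NA_integer_
  g
}

#' Cohort-relative composite categories (cognitive and social activity)
#'
#' Both composites are sums of z-scored components (equal weights); the
#' cognitive composite is cut at cohort tertiles and the social composite
#' at cohort quartiles, using midrank-based empirical quantiles with ties
#' assigned to the lower group. Loneliness is a direct recode of the survey
#' item. A `context` computed on one cohort (z parameters and cut values)
#' can be reused to categorize further records on the same scale.
#'
#' @inheritParams classify_clinical
#' @param context optionally, the `context` of a previous call.
#' @return list with `levels`, `prov` and `context`.
#' @export
composite_tertiles_quartiles <- function(data, context = NULL) {
  cog_cols <- c("cog_work_computer", "cog_leisure_computer", "cog_cultural")
  soc_cols <- c("cohabiting", "friends_help", "friends_confide",
                "neighbourhood_community", "neighbourhood_trust",
                "neighbourhood_liking", "social_participation")

  if (is.null(context)) {
    context <- list(
      cognitive = composite_context(data, cog_cols, 3),
      social = composite_context(data, soc_cols, 4)
    )
  }
  cog <- composite_apply(data, context$cognitive, factor_levels()$cognitive_activity)
  soc <- composite_apply(data, context$social, factor_levels()$social_activity)
  lonely <- ifelse(is.na(data$lonely), NA_character_,
                   ifelse(data$lonely, "yes", "no"))
  list(
    levels = tibble(cognitive_activity = cog, social_activity = soc,
                    lonely = lonely),
    prov = tibble(
      cognitive_activity = prov_if(cog, "derived"),
      social_activity = prov_if(soc, "derived"),
      lonely = prov_if(lonely, "survey")
    ),
    context = context
  )
}

component_matrix <- function(data, cols) {
  matrix(unlist(lapply(cols, function(cl) as.numeric(data[[cl]]))),
         nrow = nrow(data), dimnames = list(NULL, cols))
}

composite_score <- function(data, cols, pars) {
  m <- component_matrix(data, cols)
  z <- sweep(sweep(m, 2, pars$mean, "-"), 2, pars$sd, "/")
  rowSums(z)
}

composite_context <- function(data, cols, k) {
  m <- component_matrix(data, cols)
  mu <- colMeans(m, na.rm = TRUE)
  sig <- apply(m, 2, sd, na.rm = TRUE)
  if (nrow(m) > 1 && any(sig == 0, na.rm = TRUE)) {
    warning("constant composite component; treated as zero contribution")
  }
  sig[is.na(sig) | sig == 0] <- 1
  pars <- list(mean = mu, sd = sig, cols = cols, k = k)
  comp <- composite_score(data, cols, pars)
  g <- quantile_groups(comp, k)
  if (length(unique(stats::na.omit(g))) == 1 && sum(!is.na(g)) > 1 &&
      length(unique(stats::na.omit(comp))) == 1) {
    warning("all-constant composite: single category assigned")
  }
  # value thresholds reproducing the rank-based groups on new data
  thr <- vapply(seq_len(k - 1), function(i) {
    vals <- comp[!is.na(g) & g <= i]
    if (length(vals)) max(vals) else -Inf
  }, numeric(1))
  pars$thresholds <- thr
  pars
}

composite_apply <- function(data, pars, labels) {
  comp <- composite_score(data, pars$cols, pars)
  g <- rep(1L, length(comp))
  for (t in pars$thresholds) g <- g + (comp > t + 1e-12)
  g[is.na(comp)] <- NA_integer_
  labels[g]
}

education_level <- function(data, config) {
  if ("education" %in% names(data) && !all(is.na(data$education))) {
    lvl <- as.character(data$education)
    return(list(level = lvl, prov = prov_if(lvl, "registry")))
  }
  yrs <- data$education_years
  hi <- if (config$education_bands == "table") 11 else 12
  lvl <- ifelse(is.na(yrs), NA_character_,
                ifelse(yrs < 8, "low", ifelse(yrs <= hi, "medium", "high")))
  list(level = lvl, prov = prov_if(lvl, "registry"))
}

#' Binary outcome labels from the adjudicated outcome category
#'
#' Dementia is any dementia diagnosis vs no dementia (mild cognitive
#' impairment counts as no dementia). The AD label is AD vs no dementia,
#' with non-AD dementia set to missing so those participants drop out of
#' the AD analysis.
#'
#' @param outcome character vector with values `no_cognitive_impairment`,
#'   `aMCI`, `naMCI`, `dementia_AD`, `dementia_other`, or `NA`.
#' @return tibble with `dementia` and `ad` (`"no_dementia"` / `"dementia"` /
#'   `"ad"` / `NA`).
#' @export
outcome_labels <- function(outcome) {
  dem <- ifelse(is.na(outcome), NA_character_,
                ifelse(outcome %in% c("dementia_AD", "dementia_other"),
                       "dementia", "no_dementia"))
  ad <- ifelse(is.na(outcome), NA_character_,
               ifelse(outcome == "dementia_AD", "ad",
                      ifelse(outcome == "dementia_other", NA_character_,
                             "no_dementia")))
  tibble(dementia = dem, ad = ad)
}

#' Harmonize a raw cohort into index-ready factor levels
#'
#' Applies every classifier ([categorize_bmi()], [categorize_alcohol()],
#' [classify_clinical()], [categorize_activity()],
#' [composite_tertiles_quartiles()]) plus education banding and outcome
#' labelling, and returns one row per participant with a level column per
#' factor and a matching `<factor>_prov` provenance column
#' (`survey`, `earlier_wave`, `registry`, `derived`, or `NA` when missing).
#'
#' @inheritParams classify_clinical
#' @param context optional composite context from a previous run (used to
#'   harmonize new records on an existing cohort's scale).
#' @return a `harmonized_cohort` tibble; attributes `context` (composite
#'   cut points and z parameters) and `conflicts` (survey/registry
#'   disagreements, survey retained).
#' @export
harmonize_cohort <- function(data, registry = NULL,
                             config = harmonize_config(), context = NULL) {
  edu <- education_level(data, config)
  clin <- classify_clinical(data, registry, config)
  act <- categorize_activity(data)
  comp <- composite_tertiles_quartiles(data, context)

  out <- tibble(
    id = data$id,
    age_baseline = data$baseline_age,
    age_followup = data$follow_up_age,
    sex = as.character(data$sex),
    education = edu$level,
    alcohol = categorize_alcohol(data$alcohol_units_per_week, config),
    bmi = categorize_bmi(data$height, data$weight)
  )
  out <- dplyr::bind_cols(out, clin$levels, act$levels, comp$levels)
  out <- dplyr::bind_cols(out, outcome_labels(data$outcome))

  prov <- tibble(
    sex_prov = prov_if(out$sex, "survey"),
    education_prov = edu$prov,
    alcohol_prov = prov_if(out$alcohol, "survey"),
    bmi_prov = prov_if(out$bmi, "derived")
  )
  clin_prov <- clin$prov
  names(clin_prov) <- paste0(names(clin_prov), "_prov")
  act_prov <- act$prov
  names(act_prov) <- paste0(names(act_prov), "_prov")
  comp_prov <- comp$prov
  names(comp_prov) <- paste0(names(comp_prov), "_prov")
  out <- dplyr::bind_cols(out, prov, clin_prov, act_prov, comp_prov)

  attr(out, "context") <- comp$context
  attr(out, "conflicts") <- clin$conflicts
  class(out) <- c("harmonized_cohort", class(out))
  out
}

#' Harmonize a single record against an existing cohort context
#'
#' @param record one-row raw tibble.
#' @param cohort_context the `context` attribute of a [harmonize_cohort()]
#'   result (supplies the composite z parameters and cut points).
#' @inheritParams classify_clinical
#' @return one-row harmonized tibble.
#' @export
harmonize_record <- function(record, cohort_context, registry = NULL,
                             config = harmonize_config()) {
  if (is.null(cohort_context)) stop("cohort_context is required")
  harmonize_cohort(record, registry, config, context = cohort_context)
}
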
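raw_row <- function(...) {
  # a fully populated raw record; override fields per test
  defaults <- list(
    id = "X00001", baseline_age = 70, follow_up_age = 80.5, sex = "female",
    education = "high", height = 1.70, weight = 70,
    systolic_bp_2nd = 120, systolic_bp_3rd = 124, total_cholesterol = 5,
    non_fasting_glucose = 5, hads_depression = 3, alcohol_units_per_week = 0,
    smoking = "never", mvpa_minutes_per_week = 200, mvpa_sessions_per_week = 4,
    fish_frequency = 2L, fruit_points = 4L, vegetable_points = 4L,
    cog_work_computer = 5, cog_leisure_computer = 3, cog_cultural = 3,
    cohabiting = TRUE, friends_help = TRUE, friends_confide = TRUE,
    neighbourhood_community = 4, neighbourhood_trust = 4,
    neighbourhood_liking = 4, social_participation = 3, lonely = FALSE,
    sleep_onset = FALSE, sleep_maintenance = FALSE, sleep_early_waking = FALSE,
    hearing_loss_survey = FALSE, hearing_loss_earlier_wave = NA,
    tbi_ever_hospitalized = FALSE, stroke_self_report = FALSE,
    stroke_earlier_wave = NA, angina = FALSE, heart_failure = FALSE,
    myocardial_infarction = FALSE, other_heart_disease = FALSE,
    apoe_e4_count = 0L, diabetes_self_report = FALSE,
    outcome = "no_cognitive_impairment"
  )
  over <- list(...)
  defaults[names(over)] <- over
  tibble::as_tibble(defaults)
}

test_that("BMI categories honor the printed boundaries", {
  expect_equal(categorize_bmi(1.70, 86.7), "obese")        # BMI 30.0
  expect_equal(categorize_bmi(1.00, 18.5), "normal")       # boundary up
  expect_equal(categorize_bmi(1.80, 81.0), "overweight")   # 81/3.24 = 25.0
  expect_equal(categorize_bmi(1.80, 50.0), "underweight")
  expect_warning(out <- categorize_bmi(-1, 70), "nonpositive")
  expect_true(is.na(out))
})

test_that("alcohol bands resolve the overlapping boundary at 14 to high", {
  expect_equal(categorize_alcohol(0), "none")
  expect_equal(categorize_alcohol(7), "low_moderate")
  expect_equal(categorize_alcohol(14), "high")
  expect_equal(categorize_alcohol(20), "high")
  cfg <- harmonize_config(alcohol_boundary = "low_moderate")
  expect_equal(categorize_alcohol(14, cfg), "low_moderate")
  expect_warning(out <- categorize_alcohol(-1), "negative")
  expect_true(is.na(out))
})

test_that("clinical thresholds: HADS >= 8, SBP mean of 2nd/3rd >= 140, chol >= 6.5", {
  r <- raw_row(hads_depression = 8, systolic_bp_2nd = 140,
               systolic_bp_3rd = 142, total_cholesterol = 6.5,
               non_fasting_glucose = 9)
  cl <- classify_clinical(r)$levels
  expect_equal(cl$depression, "yes")
  expect_equal(cl$hypertension, "yes")  # mean(140, 142) = 141
  expect_equal(cl$hypercholesterolemia, "yes")
  expect_equal(cl$diabetes, "yes")      # glucose >= 9 despite no self-report
  r2 <- raw_row(systolic_bp_2nd = 138, systolic_bp_3rd = 141)
  expect_equal(classify_clinical(r2)$levels$hypertension, "no")  # mean 139.5
})

test_that("one available SBP reading is used alone", {
  r <- raw_row(systolic_bp_2nd = NA, systolic_bp_3rd = 150)
  expect_equal(classify_clinical(r)$levels$hypertension, "yes")
})

test_that("earlier-wave hearing loss carries forward when the survey is missing", {
  r <- raw_row(hearing_loss_survey = NA, hearing_loss_earlier_wave = TRUE)
  cl <- classify_clinical(r)
  expect_equal(cl$levels$hearing, "yes")
  expect_equal(cl$prov$hearing, "earlier_wave")
  # a survey answer wins over the earlier wave
  r2 <- raw_row(hearing_loss_survey = FALSE, hearing_loss_earlier_wave = TRUE)
  expect_equal(classify_clinical(r2)$levels$hearing, "no")
})

test_that("registry codes fill gaps but never override a survey answer", {
  reg <- tibble::tibble(id = "X00001", icd10 = "E11", year = 2008)
  r <- raw_row(diabetes_self_report = NA, non_fasting_glucose = NA)
  cl <- classify_clinical(r, registry = reg)
  expect_equal(cl$levels$diabetes, "yes")
  expect_equal(cl$prov$diabetes, "registry")
  # survey says no: survey wins and the disagreement is logged
  r2 <- raw_row(diabetes_self_report = FALSE, non_fasting_glucose = 5)
  cl2 <- classify_clinical(r2, registry = reg)
  expect_equal(cl2$levels$diabetes, "no")
  expect_equal(cl2$conflicts$factor, "diabetes")
  # outside the registry window the code is ignored
  reg_old <- tibble::tibble(id = "X00001", icd10 = "E11", year = 2005)
  cl3 <- classify_clinical(r, registry = reg_old)
  expect_true(is.na(cl3$levels$diabetes))
})

test_that("missing SBP without a hypertension code leaves hypertension missing", {
  r <- raw_row(systolic_bp_2nd = NA, systolic_bp_3rd = NA)
  expect_true(is.na(classify_clinical(r)$levels$hypertension))
  reg <- tibble::tibble(id = "X00001", icd10 = "I10", year = 2009)
  expect_equal(classify_clinical(r, reg)$levels$hypertension, "yes")
})

test_that("sleep disturbance is any of the three items several times a week", {
  expect_equal(classify_clinical(raw_row(sleep_maintenance = TRUE))$levels$sleep_disturbance, "yes")
  expect_equal(classify_clinical(raw_row())$levels$sleep_disturbance, "no")
  r <- raw_row(sleep_onset = NA, sleep_maintenance = FALSE,
               sleep_early_waking = FALSE)
  expect_true(is.na(classify_clinical(r)$levels$sleep_disturbance))
})

test_that("activity rules: 150 minutes is highly active, CAIDE needs two sessions", {
  a <- categorize_activity(raw_row(mvpa_minutes_per_week = 150,
                                   mvpa_sessions_per_week = 3))$levels
  expect_equal(a$physical_activity, "high")
  expect_equal(a$physical_activity_caide, "active")
  b <- categorize_activity(raw_row(mvpa_minutes_per_week = 40,
                                   mvpa_sessions_per_week = 1))$levels
  expect_equal(b$physical_activity, "medium")
  expect_equal(b$physical_activity_caide, "inactive")
  c <- categorize_activity(raw_row(mvpa_minutes_per_week = 29,
                                   mvpa_sessions_per_week = 1))$levels
  expect_equal(c$physical_activity, "low")
})

test_that("diet score of 10 is healthy and any missing component blanks it", {
  a <- categorize_activity(raw_row(fruit_points = 4L, vegetable_points = 3L,
                                   fish_frequency = 3L))$levels
  expect_equal(a$mediterranean_diet, "yes")   # 4 + 3 + 3 = 10
  b <- categorize_activity(raw_row(fruit_points = 3L, vegetable_points = 3L,
                                   fish_frequency = 3L))$levels
  expect_equal(b$mediterranean_diet, "no")    # 9
  c <- categorize_activity(raw_row(fruit_points = NA))$levels
  expect_true(is.na(c$mediterranean_diet))
  expect_equal(a$fish_intake, "2.1-4")
})

test_that("three distinct composites split one per tertile, eight split two per quartile", {
  rows <- dplyr::bind_rows(lapply(1:3, function(i) {
    raw_row(id = sprintf("X%05d", i), cog_work_computer = i,
            cog_leisure_computer = i, cog_cultural = i)
  }))
  # unspecified social items are constant in this fixture: warned, tolerated
  suppressWarnings(
    expect_warning(comp <- composite_tertiles_quartiles(rows), "constant")
  )
  expect_equal(comp$levels$cognitive_activity, c("low", "medium", "high"))

  rows8 <- dplyr::bind_rows(lapply(1:8, function(i) {
    raw_row(id = sprintf("X%05d", i), social_participation = i,
            neighbourhood_community = i / 2, neighbourhood_trust = 2,
            neighbourhood_liking = 2)
  }))
  soc <- suppressWarnings(composite_tertiles_quartiles(rows8))$levels$social_activity
  expect_equal(unname(table(soc)[factor_levels()$social_activity]),
               rep(2L, 4), ignore_attr = TRUE)
})

test_that("reported strong loneliness recodes to lonely", {
  comp <- composite_tertiles_quartiles(raw_row(lonely = TRUE))
  expect_equal(comp$levels$lonely, "yes")
})

test_that("a fully populated record harmonizes with no missing factors", {
  h <- harmonize_cohort(raw_row())
  lev <- factor_levels()
  for (f in names(lev)) {
    expect_false(is.na(h[[f]]), info = f)
    expect_true(h[[f]] %in% lev[[f]], info = f)
    expect_false(is.na(h[[paste0(f, "_prov")]]), info = f)
  }
})

test_that("education can come from banded years, with the text-variant switch", {
  r <- raw_row(education = NA, education_years = 12)
  h <- harmonize_cohort(r)
  expect_equal(h$education, "high")     # table banding: > 11 years
  h2 <- harmonize_cohort(r, config = harmonize_config(education_bands = "text"))
  expect_equal(h2$education, "medium")  # text banding: 8-12 years
})

test_that("outcome labels keep MCI as no-dementia and blank non-AD dementia for AD", {
  out <- outcome_labels(c("no_cognitive_impairment", "aMCI", "naMCI",
                          "dementia_AD", "dementia_other", NA))
  expect_equal(out$dementia, c("no_dementia", "no_dementia", "no_dementia",
                               "dementia", "dementia", NA))
  expect_equal(out$ad, c("no_dementia", "no_dementia", "no_dementia",
                         "ad", NA, NA))
})

test_that("harmonization is idempotent on back-filled synthetic records", {
  spec <- cohort_spec(n_participants = 400, seed = 31)
  raw <- generate_cohort(spec)
  h1 <- harmonize_cohort(raw)
  ctx <- attr(h1, "context")
  h2 <- harmonize_record(raw, cohort_context = ctx)
  lev <- factor_levels()
  for (f in names(lev)) {
    expect_identical(h1[[f]], h2[[f]], info = f)
  }
})

test_that("registry data never un-sets a survey-derived level", {
  spec <- cohort_spec(n_participants = 200, seed = 77)
  raw <- generate_cohort(spec)
  h_plain <- harmonize_cohort(raw)
  reg <- tibble::tibble(id = raw$id,
                        icd10 = sample(c("I10", "E11", "F32", "I63"),
                                       nrow(raw), TRUE),
                        year = 2008)
  h_reg <- harmonize_cohort(raw, registry = reg)
  for (f in c("hypertension", "diabetes", "depression", "stroke")) {
    set_before <- !is.na(h_plain[[f]])
    expect_identical(h_plain[[f]][set_before], h_reg[[f]][set_before], info = f)
  }
})
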
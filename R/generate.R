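#' Generate a synthetic participant-level cohort
#'
#' Draws a cohort with the statistical structure the downstream analysis
#' assumes. Categorical risk factors are generated by thresholding a latent
#' multivariate normal (Gaussian copula) at the quantiles implied by the
#' factor prevalences; raw continuous measurements are then back-filled
#' uniformly within the numeric interval of the assigned category (with
#' unbounded intervals truncated at physiologic limits), which guarantees
#' that harmonizing the raw record recovers the assigned category exactly.
#' The dementia outcome is Bernoulli from a logistic model on baseline age,
#' education and any subset of factors; the Mediterranean-diet category is
#' thresholded conditionally on the fish band (a diet score of 10+ is
#' unreachable in the lowest fish band), preserving its marginal prevalence.
#' Cognitive and social activity are cohort-relative composites: component
#' items are back-filled monotonically from their latent and the assigned
#' tertile/quartile is, by construction, the one the harmonizer recovers.
#'
#' @param spec a [cohort_spec()].
#' @return tibble of raw records (one row per participant) with attributes
#'   `assigned` (the generator's category assignments, for round-trip
#'   checks) and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_participants
  set.seed(spec$seed)

  R <- spec$latent_correlation
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    stop("latent correlation matrix is not positive semidefinite: ",
         "smallest eigenvalue ", format(min(ev$values), digits = 4))
  }
  A <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(R))
  Z <- matrix(rnorm(n * nrow(R)), n) %*% t(A)
  colnames(Z) <- colnames(R)

  sex <- ifelse(runif(n) < spec$female_fraction, "female", "male")
  age <- pmin(pmax(spec$age_mean + spec$age_sd * Z[, "age"],
                   spec$age_range[1]), spec$age_range[2])

  # categorical assignment by quantile thresholding
  assigned <- list(sex = sex)
  for (f in names(spec$factor_prevalences)) {
    if (f == "mediterranean_diet") next
    p <- spec$factor_prevalences[[f]]
    u <- pnorm(Z[, f])
    assigned[[f]] <- names(p)[findInterval(u, cumsum(p)[-length(p)]) + 1L]
  }

  # mediterranean diet: unreachable in the lowest fish band; conditional
  # threshold keeps the marginal prevalence
  p_yes <- spec$factor_prevalences$mediterranean_diet[["yes"]]
  u_med <- pnorm(Z[, "mediterranean_diet"])
  fish_idx <- match(assigned$fish_intake, factor_levels()$fish_intake)
  eligible <- fish_idx >= 2
  p_star <- min(1, p_yes * n / max(1, sum(eligible)))
  # empirical threshold within the eligible subset: robust to latent
  # correlation between the diet and fish factors
  thr <- if (any(eligible)) {
    quantile(u_med[eligible], p_star, type = 1, names = FALSE)
  } else {
    -Inf
  }
  assigned$mediterranean_diet <-
    ifelse(eligible & u_med <= thr, "yes", "no")

  raw <- backfill_raw(n, sex, age, assigned, Z, spec)

  # composite categories: assign exactly what the harmonizer recovers
  comp <- composite_tertiles_quartiles(raw)
  assigned$cognitive_activity <- comp$levels$cognitive_activity
  assigned$social_activity <- comp$levels$social_activity

  raw$outcome <- draw_outcome(spec, age, assigned)

  attr(raw, "assigned") <- as_tibble(assigned)
  attr(raw, "spec") <- spec
  raw
}

runif_in <- function(n, lo, hi) lo + (hi - lo) * runif(n)

backfill_raw <- function(n, sex, age, a, Z, spec) {
  lev <- factor_levels()

  # blood pressure: mean of 2nd/3rd readings inside the assigned band
  bp_mean <- ifelse(a$hypertension == "yes",
                    runif_in(n, 140.05, 210), runif_in(n, 95, 139.9))
  bp_half <- runif_in(n, 0, 4)

  bmi_lo <- c(underweight = 15, normal = 18.5, overweight = 25, obese = 30.01)
  bmi_hi <- c(underweight = 18.49, normal = 24.99, overweight = 29.99, obese = 44.9)
  bmi_val <- unname(runif_in(n, bmi_lo[a$bmi], bmi_hi[a$bmi]))
  height <- runif_in(n, 1.55, 1.90)

  alcohol <- numeric(n)
  alcohol[a$alcohol == "none"] <- 0
  k <- a$alcohol == "low_moderate"
  alcohol[k] <- runif_in(sum(k), 0.5, 13.9)
  k <- a$alcohol == "high"
  alcohol[k] <- runif_in(sum(k), 14, 40)

  hads <- ifelse(a$depression == "yes",
                 sample(8:21, n, replace = TRUE), sample(0:7, n, replace = TRUE))

  diab_yes <- a$diabetes == "yes"
  glucose <- ifelse(diab_yes, runif_in(n, 4, 12), runif_in(n, 4, 8.9))

  pa_lo <- c(low = 0, medium = 30, high = 150)
  pa_hi <- c(low = 29.9, medium = 149.9, high = 600)
  minutes <- unname(runif_in(n, pa_lo[a$physical_activity],
                             pa_hi[a$physical_activity]))
  sessions <- pmin(7, pmax(1, floor(minutes / 30)))

  fish_idx <- match(a$fish_intake, lev$fish_intake)
  med_yes <- a$mediterranean_diet == "yes"
  s_lo <- ifelse(med_yes, pmax(2, 10 - fish_idx), 2)
  s_hi <- ifelse(med_yes, 8, pmin(8, 9 - fish_idx))
  fv_sum <- s_lo + floor(runif(n) * (s_hi - s_lo + 1))
  f_lo <- pmax(1, fv_sum - 4)
  f_hi <- pmin(4, fv_sum - 1)
  fruit <- f_lo + floor(runif(n) * (f_hi - f_lo + 1))
  veg <- fv_sum - fruit

  heart_yes <- a$heart_disease == "yes"
  which_flag <- sample.int(4, n, replace = TRUE)
  heart <- sapply(1:4, function(j) heart_yes & which_flag == j)

  sleep_yes <- a$sleep_disturbance == "yes"
  first_item <- sample.int(3, n, replace = TRUE)
  extra <- matrix(runif(3 * n) < 0.35, n)
  sleep <- sapply(1:3, function(j) sleep_yes & (first_item == j | extra[, j]))

  apoe <- integer(n)
  carrier <- a$apoe4 == "carrier"
  apoe[carrier] <- ifelse(runif(sum(carrier)) < spec$apoe_homozygote_fraction, 2L, 1L)

  C <- Z[, "cognitive_activity"]
  S <- Z[, "social_activity"]

  tibble(
    id = sprintf("P%05d", seq_len(n)),
    baseline_age = age,
    follow_up_age = age + spec$followup_offset + rnorm(n, 0, 0.4),
    sex = sex,
    education = a$education,
    height = height,
    weight = bmi_val * height^2,
    systolic_bp_2nd = bp_mean - bp_half,
    systolic_bp_3rd = bp_mean + bp_half,
    total_cholesterol = ifelse(a$hypercholesterolemia == "yes",
                               runif_in(n, 6.5, 10), runif_in(n, 3.5, 6.49)),
    non_fasting_glucose = glucose,
    hads_depression = hads,
    alcohol_units_per_week = alcohol,
    smoking = a$smoking,
    mvpa_minutes_per_week = minutes,
    mvpa_sessions_per_week = sessions,
    fish_frequency = fish_idx,
    fruit_points = fruit,
    vegetable_points = veg,
    cog_work_computer = 10 * pnorm(C),
    cog_leisure_computer = 7 * pnorm(0.9 * C),
    cog_cultural = 1 + 4 * pnorm(1.1 * C),
    cohabiting = S > qnorm(0.40),
    friends_help = S > qnorm(0.20),
    friends_confide = S > qnorm(0.25),
    neighbourhood_community = 1 + 4 * pnorm(0.9 * S),
    neighbourhood_trust = 1 + 4 * pnorm(1.1 * S),
    neighbourhood_liking = 1 + 4 * pnorm(S),
    social_participation = 1 + 4 * pnorm(0.8 * S),
    lonely = a$lonely == "yes",
    sleep_onset = sleep[, 1],
    sleep_maintenance = sleep[, 2],
    sleep_early_waking = sleep[, 3],
    hearing_loss_survey = a$hearing == "yes",
    hearing_loss_earlier_wave = NA,
    tbi_ever_hospitalized = a$tbi == "yes",
    stroke_self_report = a$stroke == "yes",
    stroke_earlier_wave = NA,
    angina = heart[, 1],
    heart_failure = heart[, 2],
    myocardial_infarction = heart[, 3],
    other_heart_disease = heart[, 4],
    apoe_e4_count = apoe,
    diabetes_self_report = diab_yes
  )
}

draw_outcome <- function(spec, age, assigned) {
  om <- spec$outcome_model
  n <- length(age)
  lp <- rep(0, n)
  co <- om$coefficients
  if (!is.null(co$age)) lp <- lp + co$age * age
  if (!is.null(co$education)) {
    lp <- lp + co$education * match(assigned$education, factor_levels()$education)
  }
  for (f in names(om$factor_effects)) {
    fe <- om$factor_effects[[f]]
    lp <- lp + fe$beta * (assigned[[f]] == fe$level)
  }
  if (!is.null(om$intercept)) {
    a0 <- om$intercept
  } else {
    target <- om$target_prevalence
    a0 <- uniroot(function(a) mean(invlogit(lp + a)) - target,
                  lower = -50, upper = 50)$root
  }
  dem <- runif(n) < invlogit(lp + a0)
  subtype <- runif(n)
  out <- rep("no_cognitive_impairment", n)
  mci <- spec$mci_fractions
  out[!dem & subtype < mci[["aMCI"]]] <- "aMCI"
  out[!dem & subtype >= mci[["aMCI"]] &
        subtype < mci[["aMCI"]] + mci[["naMCI"]]] <- "naMCI"
  out[dem] <- ifelse(subtype[dem] < spec$ad_fraction, "dementia_AD", "dementia_other")
  out
}

#' Inject MAR missingness into a raw cohort
#'
#' Sets raw variables to missing with per-variable logistic probabilities
#' depending only on baseline age, sex and education (the predictors the
#' imputation stage later conditions on). Participant id and outcome are
#' never set missing; a fixed seed gives identical output.
#'
#' @param data raw cohort tibble from [generate_cohort()].
#' @param model per-variable model list: each element
#'   `list(intercept=, age=, female=, education=)` on the log-odds scale
#'   (age per year centered at `age_center`, female indicator, education as
#'   ordered level 1-3). Either a named list under `variables`, or a flat
#'   named list of such models. Defaults to the spec's missingness model
#'   when the cohort carries one.
#' @param seed integer seed.
#' @param age_center centering constant for the age term (years).
#' @return the cohort with missing cells, plus attribute
#'   `missingness_rates` (realized per-variable rates).
#' @export
inject_missingness <- function(data, model = NULL, seed = 1L, age_center = 66.6) {
  spec <- attr(data, "spec")
  model <- model %||% (if (!is.null(spec)) spec$missingness_model)
  if (is.null(model)) stop("no missingness model supplied")
  vars <- model$variables %||% model
  vars <- vars[setdiff(names(vars), c("default", "id", "outcome"))]
  allowed <- c("intercept", "age", "female", "education")
  for (v in names(vars)) {
    extra <- setdiff(names(vars[[v]]), allowed)
    if (length(extra)) {
      stop("missingness model for '", v, "' uses unsupported predictor: ",
           extra[1], " (only age, sex, education are allowed)")
    }
    if (!v %in% names(data)) stop("unknown variable in missingness model: ", v)
  }
  set.seed(seed)
  edu_num <- match(as.character(data$education), factor_levels()$education)
  rates <- numeric(0)
  for (v in names(vars)) {
    m <- vars[[v]]
    lp <- (m$intercept %||% -Inf) +
      (m$age %||% 0) * (data$baseline_age - age_center) +
      (m$female %||% 0) * (data$sex == "female") +
      (m$education %||% 0) * edu_num
    p <- invlogit(lp)
    hit <- runif(nrow(data)) < p
    data[[v]][hit] <- NA
    rates[v] <- mean(hit)
    if (all(is.na(data[[v]]))) {
      warning("variable '", v, "' is entirely missing after injection")
    }
  }
  attr(data, "missingness_rates") <- rates
  data
}
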
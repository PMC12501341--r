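# Shared fixtures and independent oracles. Everything here is built in
# code at test time; the oracles deliberately avoid the implementation
# paths they check.

WT <- load_weight_table()

# a complete harmonized profile; defaults are overridable per test
make_profile <- function(..., id = "T00001", age = 70, sex = "female") {
  defaults <- list(
    education = "high", alcohol = "none", apoe4 = "non_carrier",
    bmi = "normal", cognitive_activity = "low", heart_disease = "no",
    depression = "no", diabetes = "no", fish_intake = "0-0.25",
    mediterranean_diet = "no", hearing = "no", hypercholesterolemia = "no",
    hypertension = "no", physical_activity = "low",
    physical_activity_caide = "active", tbi = "no", sleep_disturbance = "no",
    smoking = "never", social_activity = "lowest", lonely = "no",
    stroke = "no"
  )
  over <- list(...)
  defaults[names(over)] <- over
  tibble::as_tibble(c(list(id = id, age_baseline = age, sex = sex), defaults))
}

# random complete profiles over the full level vocabulary
random_profiles <- function(n, seed = 1) {
  set.seed(seed)
  lev <- factor_levels()
  lev$sex <- NULL
  cols <- lapply(lev, function(l) sample(l, n, replace = TRUE))
  tibble::as_tibble(c(
    list(id = sprintf("R%05d", seq_len(n)),
         age_baseline = runif(n, 40, 100),
         sex = sample(c("female", "male"), n, replace = TRUE)),
    cols
  ))
}

# brute-force scoring oracle: loop over weight entries, check each match
# condition explicitly, sum as plain doubles
oracle_score <- function(profile, index, weights, include_demographics = TRUE) {
  w <- weights[weights$index == index, ]
  if (!include_demographics) w <- w[!w$demographic, ]
  total <- 0
  for (i in seq_len(nrow(w))) {
    e <- w[i, ]
    if (e$factor == "age") {
      if (!is.na(e$sex) && e$sex != profile$sex) next
      if (floor(profile$age_baseline) >= e$age_min &&
          floor(profile$age_baseline) <= e$age_max) {
        total <- total + e$points
      }
    } else {
      if (!is.na(e$sex) && e$sex != profile$sex) next
      if (profile[[e$factor]] == e$level) total <- total + e$points
    }
  }
  total
}

# exhaustive pair-count AUC oracle with half-credit for ties
oracle_auc <- function(pred, y) {
  cases <- pred[y == 1]
  controls <- pred[y == 0]
  s <- 0
  for (x in cases) for (z in controls) {
    s <- s + (x > z) + 0.5 * (x == z)
  }
  s / (length(cases) * length(controls))
}

# brute-force range oracle: enumerate every level combination of a small
# factor subset (and both sexes when any entry is sex-conditioned)
oracle_range <- function(weights, index, factors, include_demographics = TRUE) {
  w <- weights[weights$index == index & weights$factor %in% factors, ]
  if (!include_demographics) w <- w[!w$demographic, ]
  lev <- factor_levels()
  sexes <- if (any(!is.na(w$sex))) c("female", "male") else NA_character_
  vals <- c()
  for (s in sexes) {
    ws <- w[is.na(w$sex) | (!is.na(s) & w$sex == s), ]
    fac <- unique(ws$factor)
    choices <- lapply(fac, function(f) {
      e <- ws[ws$factor == f, ]
      split(e$points, seq_len(nrow(e)))
    })
    grid <- expand.grid(lapply(choices, seq_along))
    for (r in seq_len(nrow(grid))) {
      tot <- 0
      for (j in seq_along(fac)) {
        tot <- tot + choices[[j]][[grid[r, j]]]
      }
      vals <- c(vals, tot)
    }
  }
  c(min = min(vals), max = max(vals))
}
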
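test_that("weight tables load, cover every level, and omit dropped items", {
  expect_s3_class(WT, "weight_table")
  expect_setequal(unique(WT$index), index_names())
  expect_false(any(grepl("pesticide|kidney", WT$factor)))
  # demographic flags only on sex / age / education
  expect_true(all(WT$factor[WT$demographic] %in% c("sex", "age", "education")))
  # LIBRA and LIBRA2 demographic entries are borrowed
  lib <- WT[WT$index %in% c("LIBRA", "LIBRA2") & WT$demographic, ]
  expect_true(all(lib$borrowed))
})

test_that("duplicate or gapped coverage fails the load with the cell named", {
  d <- tempfile()
  dir.create(d)
  writeLines(c(
    "index: TEST",
    "entries:",
    "  - {factor: depression, level: 'no', points: 0}",
    "  - {factor: depression, level: 'no', points: 1}",
    "  - {factor: depression, level: 'yes', points: 2}"
  ), file.path(d, "test.yaml"))
  expect_error(load_weight_table(d), "duplicate.*depression")
  writeLines(c(
    "index: TEST",
    "entries:",
    "  - {factor: depression, level: 'yes', points: 2}"
  ), file.path(d, "test.yaml"))
  expect_error(load_weight_table(d), "gapped.*depression.*no")
})

test_that("single-cell weight lookups match the published table", {
  lookup <- function(ix, f, l, s = NA) {
    w <- WT[WT$index == ix & WT$factor == f & WT$level == l, ]
    if (!is.na(s)) w <- w[w$sex == s, ]
    w$points
  }
  expect_equal(lookup("CAIDE", "sex", "male"), 1)
  expect_equal(lookup("CAIDE", "apoe4", "carrier"), 2)
  expect_equal(lookup("LIBRA", "bmi", "normal"), 0)
  expect_equal(lookup("CogDrisk", "diabetes", "yes", "male"), 2)
  expect_equal(lookup("CogDrisk", "diabetes", "yes", "female"), 3)
})

test_that("the obese level scores 5 / 2 / 3 / 1.6 / 7 across the indices", {
  p <- make_profile(bmi = "obese")
  vals <- vapply(index_names(), function(ix) {
    score_index(p, ix, WT, include_demographics = FALSE)$value
  }, numeric(1))
  base <- vapply(index_names(), function(ix) {
    score_index(make_profile(), ix, WT, include_demographics = FALSE)$value
  }, numeric(1))
  expect_equal(unname(vals - base),
               c(5, 2, 3, 1.6, 7))
})

test_that("LIBRA sums obese + hypertensive + current smoker to 4.7", {
  p <- make_profile(bmi = "obese", hypertension = "yes", smoking = "current")
  base <- score_index(make_profile(), "LIBRA", WT,
                      include_demographics = FALSE)$value
  val <- score_index(p, "LIBRA", WT, include_demographics = FALSE)$value
  expect_equal(val - base, 1.6 + 1.6 + 1.5)
})

test_that("a profile at per-index zero-weight levels scores exactly zero", {
  for (ix in index_names()) {
    w <- WT[WT$index == ix & !WT$demographic, ]
    zero_levels <- list()
    for (f in setdiff(unique(w$factor), "age")) {
      e <- w[w$factor == f & w$points == 0, ]
      expect_gt(nrow(e), 0)  # every factor carries a zero reference level
      zero_levels[[f]] <- e$level[1]
    }
    p <- do.call(make_profile, zero_levels)
    expect_equal(
      score_index(p, ix, WT, include_demographics = FALSE)$value, 0,
      info = ix
    )
  }
})

test_that("scores agree exactly with the brute-force oracle on 1000 random profiles", {
  profs <- random_profiles(1000, seed = 99)
  for (ix in index_names()) {
    for (demo in c(TRUE, FALSE)) {
      got <- score_index(profs, ix, WT, include_demographics = demo)$value
      want <- vapply(seq_len(nrow(profs)), function(i) {
        oracle_score(profs[i, ], ix, WT, include_demographics = demo)
      }, numeric(1))
      # exact after canonical 2-decimal rounding: the implementation sums
      # scaled integers, the oracle sums doubles in entry order
      expect_identical(got, round(want, 2))
    }
  }
})

test_that("with-demographics minus without equals the demographic-only sum", {
  profs <- random_profiles(200, seed = 3)
  for (ix in index_names()) {
    with_d <- score_index(profs, ix, WT, include_demographics = TRUE)$value
    without <- score_index(profs, ix, WT, include_demographics = FALSE)$value
    demo_only <- vapply(seq_len(nrow(profs)), function(i) {
      oracle_score(profs[i, ], ix, WT, TRUE) -
        oracle_score(profs[i, ], ix, WT, FALSE)
    }, numeric(1))
    expect_equal(with_d - without, demo_only)
  }
})

test_that("switching a factor to a higher-point level never lowers the score", {
  set.seed(4)
  profs <- random_profiles(50, seed = 4)
  for (ix in index_names()) {
    w <- WT[WT$index == ix & !WT$demographic & WT$factor != "age", ]
    for (i in 1:10) {
      p <- profs[sample(nrow(profs), 1), ]
      f <- sample(unique(w$factor), 1)
      e <- w[w$factor == f, ]
      if (any(!is.na(e$sex))) e <- e[e$sex == p$sex, ]
      e <- e[order(e$points), ]
      lo <- p; lo[[f]] <- e$level[1]
      hi <- p; hi[[f]] <- e$level[nrow(e)]
      expect_gte(score_index(hi, ix, WT)$value,
                 score_index(lo, ix, WT)$value)
    }
  }
})

test_that("every random profile scores inside the theoretical range", {
  profs <- random_profiles(300, seed = 12)
  for (ix in index_names()) {
    rng <- theoretical_range(ix, WT)
    vals <- score_index(profs, ix, WT)$value
    expect_true(all(vals >= rng["min"] - 1e-9 & vals <= rng["max"] + 1e-9))
  }
})

test_that("theoretical minima reproduce the published score floors", {
  # the most protective LIBRA combination sums -1 - 1.7 - 3.2 = -5.9 and
  # the CogDrisk floor is -0.25 - 5 - 3 = -8.25; both hold with borrowed
  # demographics included because the youngest/highest bands carry 0
  expect_equal(unname(theoretical_range("LIBRA", WT)["min"]), -5.9)
  expect_equal(unname(theoretical_range("CogDrisk", WT)["min"]), -8.25)
  expect_equal(unname(theoretical_range("LIBRA2", WT, FALSE)["min"]), 0)
})

test_that("CAIDE max with demographics dominates the max without", {
  expect_gte(theoretical_range("CAIDE", WT, TRUE)["max"],
             theoretical_range("CAIDE", WT, FALSE)["max"])
})

test_that("complete-case scoring blanks the score when a covered factor is missing", {
  p <- make_profile()
  p$hearing <- NA_character_
  # hearing is covered only by LIBRA2
  expect_true(is.na(score_index(p, "LIBRA2", WT)$value))
  expect_false(is.na(score_index(p, "CAIDE", WT)$value))
  perm <- score_index(p, "LIBRA2", WT, mode = "permissive")
  expect_false(is.na(perm$value))
  expect_equal(perm$missing_factors, "hearing")
  expect_equal(perm$n_factors_missing, 1)
})

test_that("score_cohort builds main-analysis and available-case subsets", {
  profs <- random_profiles(10, seed = 7)
  profs$hearing[1] <- NA_character_        # LIBRA2 only
  profs$depression[2] <- NA_character_     # several indices
  profs$apoe4[3] <- NA_character_          # CAIDE only
  rep <- score_cohort(profs, WT)
  expect_length(rep$complete_case_ids, 7)
  expect_false(profs$id[1] %in% rep$available_ids$LIBRA2)
  expect_true(profs$id[1] %in% rep$available_ids$CAIDE)
  expect_false(profs$id[3] %in% rep$available_ids$CAIDE)
  expect_true(profs$id[3] %in% rep$available_ids$LIBRA)
  # complete cohort: all-indices subset equals the full cohort
  full <- score_cohort(random_profiles(10, seed = 8), WT)
  expect_length(full$complete_case_ids, 10)
  expect_error(score_cohort(profs[0, ], WT), "empty")
})

test_that("per-cell overrides replace points and reject unknown cells", {
  wt2 <- load_weight_table(overrides = data.frame(
    index = "CAIDE", factor = "apoe4", level = "carrier", points = 3
  ))
  expect_equal(wt2$points[wt2$index == "CAIDE" & wt2$factor == "apoe4" &
                            wt2$level == "carrier"], 3)
  expect_error(
    load_weight_table(overrides = data.frame(
      index = "CAIDE", factor = "apoe4", level = "nonsense", points = 3
    )),
    "matches no weight entry"
  )
})
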
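#' Score a cohort of harmonized profiles on one index
#'
#' Sums the weight-table points matched by each profile's factor levels.
#' Age-banded entries are resolved on attained whole years of baseline age
#' (and sex where the bands are sex-specific); demographic entries (sex,
#' age, education) are included only when `include_demographics = TRUE`.
#' Internally sums run on integer points scaled by 100, so results are
#' exact and independent of summation order.
#'
#' @param profiles tibble of harmonized profiles: `id`, `age_baseline`, and
#'   one column per factor with levels from [factor_levels()].
#' @param index one of [index_names()].
#' @param weights a `weight_table` from [load_weight_table()].
#' @param include_demographics include the sex/age/education entries?
#' @param mode `"complete"` (default): the score is `NA` whenever any
#'   covered factor is missing. `"permissive"`: missing factors contribute
#'   0 points and are listed in `missing_factors`.
#' @return tibble: `id`, `index`, `value`, `n_factors_scored`,
#'   `n_factors_missing`, `missing_factors` (comma-separated).
#' @export
score_index <- function(profiles, index, weights = load_weight_table(),
                        include_demographics = TRUE,
                        mode = c("complete", "permissive")) {
  mode <- match.arg(mode)
  if (!index %in% weights$index) stop("unknown index: ", index)
  n <- nrow(profiles)
  w <- weights[weights$index == index, ]
  if (!include_demographics) w <- w[!w$demographic, ]

  facs <- setdiff(unique(w$factor), "age")
  has_age <- "age" %in% w$factor
  total <- rep(0L, n)
  miss <- matrix(FALSE, n, length(facs) + has_age)
  labels <- c(facs, if (has_age) "age")

  for (j in seq_along(facs)) {
    f <- facs[j]
    e <- w[w$factor == f, ]
    val <- as.character(profiles[[f]])
    if (all(is.na(e$sex))) {
      pts <- e$points_scaled[match(val, e$level)]
    } else {
      key <- paste(val, as.character(profiles[["sex"]]))
      pts <- e$points_scaled[match(key, paste(e$level, e$sex))]
    }
    bad <- !is.na(val) & is.na(pts) &
      (all(is.na(e$sex)) | !is.na(profiles[["sex"]]))
    if (any(bad)) {
      stop("unknown level '", val[bad][1], "' for factor '", f, "'")
    }
    miss[, j] <- is.na(pts)
    total <- total + ifelse(is.na(pts), 0L, pts)
  }

  if (has_age) {
    e <- w[w$factor == "age", ]
    agei <- floor(as.numeric(profiles[["age_baseline"]]))
    pts <- rep(NA_integer_, n)
    for (k in seq_len(nrow(e))) {
      hit <- !is.na(agei) & agei >= e$age_min[k] & agei <= e$age_max[k]
      if (!is.na(e$sex[k])) {
        hit <- hit & !is.na(profiles[["sex"]]) & profiles[["sex"]] == e$sex[k]
      }
      pts[hit] <- e$points_scaled[k]
    }
    miss[, ncol(miss)] <- is.na(pts)
    total <- total + ifelse(is.na(pts), 0L, pts)
  }

  n_miss <- rowSums(miss)
  value <- total / 100
  if (mode == "complete") value[n_miss > 0] <- NA_real_
  miss_list <- apply(miss, 1, function(r) paste(labels[r], collapse = ","))

  tibble(
    id = profiles$id,
    index = index,
    value = value,
    n_factors_scored = length(labels) - n_miss,
    n_factors_missing = n_miss,
    missing_factors = miss_list
  )
}

#' Score a cohort on all indices, with completeness reporting
#'
#' @inheritParams score_index
#' @param indices indices to score (default all five).
#' @return a `score_report` list: `scores` (long tibble over indices),
#'   `wide` (one row per participant, one column per index),
#'   `complete_case_ids` (participants complete for every index — the main
#'   analysis sample), `available_ids` (per-index available-case id sets),
#'   and `missingness` (count of missing participants per index and factor).
#' @export
score_cohort <- function(profiles, weights = load_weight_table(),
                         indices = index_names(),
                         include_demographics = TRUE,
                         mode = c("complete", "permissive")) {
  if (nrow(profiles) == 0) stop("empty cohort")
  mode <- match.arg(mode)
  scores <- dplyr::bind_rows(lapply(
    indices, score_index,
    profiles = profiles, weights = weights,
    include_demographics = include_demographics, mode = mode
  ))
  wide <- tidyr::pivot_wider(
    scores[, c("id", "index", "value")],
    names_from = "index", values_from = "value"
  )
  ok <- stats::complete.cases(wide[, indices, drop = FALSE])
  available <- lapply(stats::setNames(indices, indices), function(ix) {
    wide$id[!is.na(wide[[ix]])]
  })
  missingness <- scores |>
    dplyr::filter(.data$n_factors_missing > 0) |>
    dplyr::count(.data$index, .data$missing_factors, name = "n_participants")
  structure(
    list(
      scores = scores, wide = wide,
      complete_case_ids = wide$id[ok],
      available_ids = available,
      missingness = missingness,
      include_demographics = include_demographics, mode = mode
    ),
    class = "score_report"
  )
}

#' Theoretical score range of an index
#'
#' Exact minimum and maximum attainable score, computed by per-factor
#' extreme selection (valid because the score is additively separable
#' across factors). Sex-conditioned entries (age bands, sex-specific
#' diabetes) are resolved by scanning both sexes and taking the overall
#' extremes over sex-consistent selections.
#'
#' @inheritParams score_index
#' @return named numeric vector `c(min = , max = )` in points.
#' @export
theoretical_range <- function(index, weights = load_weight_table(),
                              include_demographics = TRUE) {
  w <- weights[weights$index == index, ]
  if (nrow(w) == 0) stop("unknown index: ", index)
  if (!include_demographics) w <- w[!w$demographic, ]
  if (nrow(w) == 0) return(c(min = 0, max = 0))
  sexes <- if (any(!is.na(w$sex))) c("female", "male") else NA_character_
  per_sex <- vapply(sexes, function(s) {
    lo <- hi <- 0L
    for (f in unique(w$factor)) {
      e <- w[w$factor == f, ]
      if (any(!is.na(e$sex))) e <- e[e$sex == s, ]
      lo <- lo + min(e$points_scaled)
      hi <- hi + max(e$points_scaled)
    }
    c(lo, hi)
  }, numeric(2))
  c(min = min(per_sex[1, ]) / 100, max = max(per_sex[2, ]) / 100)
}
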
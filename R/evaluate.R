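safe_index <- function(x) gsub("-", "_", x)

#' Assemble the analytic data set
#'
#' Scores a harmonized cohort on every index (with and without demographic
#' weights), attaches the binary outcomes and model covariates, and
#' restricts to the main-analysis sample: participants with complete data
#' across all indices and a classified outcome.
#'
#' @param harmonized a [harmonize_cohort()] result.
#' @param weights a [load_weight_table()].
#' @param indices indices to include.
#' @return an `analysis_set` tibble: `id`, `age`, `education_num`, `sex`,
#'   `apoe4`, `dementia`/`ad` (0/1, `ad` NA for non-AD dementia), and
#'   `score_with_*` / `score_without_*` columns. Attributes: `score_report`
#'   objects for both variants and the full pre-restriction table.
#' @export
build_analysis_set <- function(harmonized, weights = load_weight_table(),
                               indices = index_names()) {
  sw <- score_cohort(harmonized, weights, indices, include_demographics = TRUE)
  so <- score_cohort(harmonized, weights, indices, include_demographics = FALSE)
  wide_w <- sw$wide
  names(wide_w)[-1] <- paste0("score_with_", safe_index(names(wide_w)[-1]))
  wide_o <- so$wide
  names(wide_o)[-1] <- paste0("score_without_", safe_index(names(wide_o)[-1]))

  base <- tibble(
    id = harmonized$id,
    age = harmonized$age_baseline,
    education_num = match(harmonized$education, factor_levels()$education),
    sex = harmonized$sex,
    apoe4 = harmonized$apoe4,
    dementia = ifelse(is.na(harmonized$dementia), NA_integer_,
                      as.integer(harmonized$dementia == "dementia")),
    ad = ifelse(is.na(harmonized$ad), NA_integer_,
                as.integer(harmonized$ad == "ad"))
  )
  full <- dplyr::left_join(dplyr::left_join(base, wide_w, by = "id"),
                           wide_o, by = "id")
  keep <- full$id %in% sw$complete_case_ids & !is.na(full$dementia) &
    !is.na(full$age) & !is.na(full$education_num)
  out <- full[keep, ]
  attr(out, "score_report_with") <- sw
  attr(out, "score_report_without") <- so
  attr(out, "full") <- full
  class(out) <- c("analysis_set", class(out))
  out
}

score_col <- function(index, include_demographics) {
  paste0(if (include_demographics) "score_with_" else "score_without_",
         safe_index(index))
}

#' Evaluate the indices against one outcome
#'
#' For each index: z-standardizes the score (mean 0, SD 1 on the supplied
#' sample, or with externally supplied parameters for stratified reuse),
#' fits a logistic model of the outcome on the standardized score (the
#' reported OR is per SD of the index), and fits the demographics-only
#' reference model (age in years plus education as an ordered numeric
#' level). Predicted risks of all models then enter the gated DeLong
#' comparison with the demographics model as reference.
#'
#' @param analysis an [build_analysis_set()] tibble (or a stratum of one).
#' @param outcome `"dementia"` or `"ad"` (AD analyses drop non-AD dementia
#'   rows, which carry `NA` in the `ad` column).
#' @param include_demographics score variant to evaluate.
#' @param indices indices to include.
#' @param z_params optional named list (index -> `list(mean=, sd=)`) reusing
#'   standardization parameters from the full sample.
#' @param global_models passed to [delong_compare()].
#' @return an `index_evaluation` list: `fits` (per-index OR per SD, 95% CI,
#'   p, stars, McFadden pseudo R-squared, n), `reference_fit`, `roc`
#'   (a `roc_comparison`), `n`, `z_params`.
#' @export
evaluate_cohort <- function(analysis, outcome = c("dementia", "ad"),
                            include_demographics = TRUE,
                            indices = index_names(), z_params = NULL,
                            global_models = "all") {
  outcome <- match.arg(outcome)
  y <- analysis[[outcome]]
  keep <- !is.na(y)
  dat <- analysis[keep, ]
  y <- y[keep]

  fits <- list()
  preds <- list()
  zp <- list()
  for (ix in indices) {
    s <- dat[[score_col(ix, include_demographics)]]
    pz <- z_params[[ix]]
    zs <- zstandardize(s, center = pz$mean, scale = pz$sd)
    zp[[ix]] <- list(mean = zs$mean, sd = zs$sd)
    f <- fit_logistic(y, data.frame(score = zs$z), model_id = ix)
    fits[[ix]] <- f
    preds[[ix]] <- f$fitted
  }
  ref <- fit_logistic(y, data.frame(age = dat$age, education = dat$education_num),
                      model_id = "Demographics")
  preds[["Demographics"]] <- ref$fitted

  fit_tab <- dplyr::bind_rows(lapply(fits, function(f) {
    row <- f$tidy[f$tidy$term == "score", ]
    tibble(model = f$model_id, or = row$or, ci_low = row$ci_low,
           ci_high = row$ci_high, p = row$p, stars = star_flags(row$p),
           pseudo_r2 = f$pseudo_r2, n = f$n)
  }))

  roc <- delong_compare(as.data.frame(preds, check.names = FALSE), y,
                        reference = "Demographics",
                        global_models = global_models)
  structure(
    list(fits = fit_tab, reference_fit = ref, roc = roc,
         n = length(y), outcome = outcome,
         include_demographics = include_demographics, z_params = zp),
    class = "index_evaluation"
  )
}

#' Run all outcome-by-demographics analysis variants
#'
#' The four main blocks: {dementia, AD} x {with, without demographic
#' weights}. AD analyses drop participants with non-AD dementia before
#' fitting.
#'
#' @inheritParams evaluate_cohort
#' @return named list of [evaluate_cohort()] results
#'   (`dementia`, `dementia_no_demographics`, `ad`, `ad_no_demographics`).
#' @export
run_outcome_variants <- function(analysis, indices = index_names()) {
  list(
    dementia = evaluate_cohort(analysis, "dementia", TRUE, indices),
    dementia_no_demographics = evaluate_cohort(analysis, "dementia", FALSE, indices),
    ad = evaluate_cohort(analysis, "ad", TRUE, indices),
    ad_no_demographics = evaluate_cohort(analysis, "ad", FALSE, indices)
  )
}

stratum_assignments <- function(analysis, axis, age_cut = 65) {
  switch(axis,
    sex = list(Female = analysis$sex == "female",
               Male = analysis$sex == "male"),
    age_group = stats::setNames(
      list(analysis$age < age_cut, analysis$age >= age_cut),
      c(sprintf("<=%d Years", age_cut - 1), sprintf(">=%d Years", age_cut))
    ),
    apoe4 = list(`APOE4 Negative` = analysis$apoe4 == "non_carrier",
                 `APOE4 Positive` = analysis$apoe4 == "carrier"),
    stop("unknown stratification axis: ", axis)
  )
}

#' Stratified analyses
#'
#' Refits the index models and the demographics reference within each
#' stratum of the requested axes (all-cause dementia, with-demographics
#' scores). Standardization parameters are estimated on the full analytic
#' sample and reused within strata by default, keeping per-SD odds ratios
#' comparable across strata; set `z_policy = "stratum"` to re-standardize
#' within each stratum instead.
#'
#' @inheritParams evaluate_cohort
#' @param axes any of `"sex"`, `"age_group"`, `"apoe4"`.
#' @param age_cut boundary for the age axis (default: under 65 vs 65+).
#' @param z_policy `"cohort"` (default) or `"stratum"`.
#' @return named list (axis -> stratum -> `index_evaluation`); strata with
#'   a single outcome class are skipped with a warning.
#' @export
run_stratified <- function(analysis, axes = c("sex", "age_group", "apoe4"),
                           indices = index_names(), age_cut = 65,
                           z_policy = c("cohort", "stratum")) {
  z_policy <- match.arg(z_policy)
  full_eval <- evaluate_cohort(analysis, "dementia", TRUE, indices)
  zp <- if (z_policy == "cohort") full_eval$z_params else NULL
  out <- list()
  for (axis in axes) {
    strata <- stratum_assignments(analysis, axis, age_cut)
    res <- list()
    for (s in names(strata)) {
      rows <- strata[[s]] & !is.na(strata[[s]])
      sub <- analysis[rows, ]
      if (length(unique(stats::na.omit(sub$dementia))) < 2) {
        warning("stratum '", s, "' has a single outcome class; skipped")
        next
      }
      res[[s]] <- evaluate_cohort(sub, "dementia", TRUE, indices, z_params = zp)
    }
    out[[axis]] <- res
  }
  out
}
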
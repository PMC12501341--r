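#' Descriptive contrast of two groups from level counts
#'
#' Builds the descriptive-table contrast (level counts and one-decimal
#' percentages for an included and an excluded group, with a Pearson
#' chi-square per factor and star flags at 0.05 / 0.005 / 0.001).
#' Percentages are computed per group column and rounded half-up, the
#' table-style convention.
#'
#' @param included,excluded named lists: factor -> named level counts.
#' @return tibble: `factor`, `level`, `n_included`, `pct_included`,
#'   `n_excluded`, `pct_excluded`, `chi2`, `df`, `p`, `stars`, `note`.
#' @export
contrast_counts <- function(included, excluded) {
  rows <- lapply(intersect(names(included), names(excluded)), function(f) {
    ci <- unlist(included[[f]])
    ce <- unlist(excluded[[f]])
    levs <- names(ci)
    ce <- ce[levs]
    tot_i <- sum(ci); tot_e <- sum(ce)
    tab <- rbind(ci, ce)
    expected_zero <- any(outer(rowSums(tab), colSums(tab)) == 0)
    if (expected_zero) {
      chi2 <- NA_real_; df <- NA_integer_; p <- NA_real_
      note <- "chi-square suppressed: zero expected cell count"
    } else {
      ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
      chi2 <- unname(ct$statistic); df <- unname(ct$parameter)
      p <- unname(ct$p.value); note <- ""
    }
    tibble(
      factor = f, level = levs,
      n_included = unname(ci),
      pct_included = as.numeric(fmt_pct(unname(ci), tot_i)),
      n_excluded = unname(ce),
      pct_excluded = as.numeric(fmt_pct(unname(ce), tot_e)),
      chi2 = chi2, df = df, p = p, stars = star_flags(p), note = note
    )
  })
  dplyr::bind_rows(rows)
}

#' Descriptive contrast of included vs excluded participants
#'
#' Counts harmonized factor levels in two disjoint participant sets and
#' delegates to [contrast_counts()].
#'
#' @param included,excluded harmonized tibbles (disjoint participants).
#' @param factors factor columns to contrast (default: all shared
#'   harmonized factors).
#' @return the [contrast_counts()] tibble.
#' @export
describe_sample <- function(included, excluded, factors = NULL) {
  if (length(intersect(included$id, excluded$id))) {
    stop("included and excluded sets must be disjoint")
  }
  lev <- factor_levels()
  factors <- factors %||%
    intersect(names(lev), intersect(names(included), names(excluded)))
  count_levels <- function(data) {
    out <- list()
    for (f in factors) {
      cnt <- table(base::factor(data[[f]], levels = lev[[f]]))
      out[[f]] <- stats::setNames(as.integer(cnt), names(cnt))
    }
    out
  }
  contrast_counts(count_levels(included), count_levels(excluded))
}

#' Sample-flow summary from design counts
#'
#' Reproduces the cohort-flow percentages from the stage counts: share of
#' the follow-up sample with a classified outcome, share of those with
#' baseline participation, the analytic sample's sex and dementia split,
#' dementia prevalence among excluded participants, and the AD-analysis
#' sample size after dropping non-AD dementia cases.
#'
#' @param config cohort calibration list (default: shipped calibration).
#' @return tibble with `quantity`, `numerator`, `denominator`, `value`.
#' @export
sample_flow <- function(config = default_cohort_config()) {
  fl <- config$sample_flow
  ci <- config$counts_included
  ce <- config$counts_excluded
  n_inc <- config$n_participants
  n_exc <- config$n_excluded
  rows <- list(
    c("pct_outcome_classified", fl$outcome_classified, fl$followup_participants),
    c("pct_baseline_participation", fl$baseline_participants, fl$outcome_classified),
    c("pct_women_included", ci$sex$female, n_inc),
    c("pct_dementia_included", ci$dementia$dementia, n_inc),
    c("pct_dementia_excluded", ce$dementia$dementia, n_exc)
  )
  out <- dplyr::bind_rows(lapply(rows, function(r) {
    tibble(quantity = r[1], numerator = as.numeric(r[2]),
           denominator = as.numeric(r[3]),
           value = as.numeric(fmt_pct(as.numeric(r[2]), as.numeric(r[3]))))
  }))
  dplyr::bind_rows(out, tibble(
    quantity = "n_ad_analysis",
    numerator = n_inc - fl$non_ad_dementia_cases,
    denominator = NA_real_,
    value = n_inc - fl$non_ad_dementia_cases
  ))
}

#' Configuration of a full pipeline run
#'
#' @param n cohort size to simulate.
#' @param seed master seed; every stage derives its own seed from it.
#' @param missingness inject MAR missingness before harmonization?
#' @param imputation run the imputed-data sensitivity stage?
#' @param m number of imputations for the sensitivity stage.
#' @param strata stratification axes.
#' @param indices indices to analyze.
#' @param age_cut stratification age boundary.
#' @param outdir optional output directory for report files.
#' @param spec_args extra arguments passed to [cohort_spec()].
#' @return a `run_config` list.
#' @export
run_config <- function(n = 5247, seed = 20260101, missingness = TRUE,
                       imputation = TRUE, m = 20,
                       strata = c("sex", "age_group", "apoe4"),
                       indices = index_names(), age_cut = 65,
                       outdir = NULL, spec_args = list()) {
  structure(list(n = n, seed = seed, missingness = missingness,
                 imputation = imputation, m = m, strata = strata,
                 indices = indices, age_cut = age_cut, outdir = outdir,
                 spec_args = spec_args),
            class = "run_config")
}

#' Run the full pipeline: simulate, harmonize, score, evaluate, impute
#'
#' Executes every stage in order on a synthetic cohort and assembles the
#' report tables: sample flow, descriptive included-vs-excluded contrast,
#' the association table (OR per SD, pseudo R-squared, by outcome and
#' demographics variant, plus strata), the AUC comparison table, and the
#' sensitivity tables (pooled imputation and index-specific available
#' case). Identical configuration (including seed) gives identical tables.
#'
#' @param config a [run_config()].
#' @param weights a [load_weight_table()].
#' @return a `run_report` list; when `config$outdir` is set the tables are
#'   also written as TSV/JSON under that directory.
#' @export
run_all <- function(config = run_config(), weights = load_weight_table()) {
  stopifnot(inherits(config, "run_config"))
  log <- list()
  stage_seed <- function(k) derive_seed(config$seed, k)

  spec <- do.call(cohort_spec, c(
    list(n_participants = config$n, seed = stage_seed(1)), config$spec_args
  ))
  raw <- generate_cohort(spec)
  log$generated <- nrow(raw)

  if (config$missingness) {
    raw <- inject_missingness(raw, seed = stage_seed(2))
    log$missingness_rates <- attr(raw, "missingness_rates")
  }

  harmonized <- harmonize_cohort(raw)
  analysis <- build_analysis_set(harmonized, weights, config$indices)
  log$analytic_n <- nrow(analysis)

  included <- harmonized[harmonized$id %in% analysis$id, ]
  excluded <- harmonized[!harmonized$id %in% analysis$id, ]
  descriptive <- if (nrow(excluded) > 0) {
    describe_sample(included, excluded)
  } else {
    NULL
  }

  variants <- run_outcome_variants(analysis, config$indices)
  strata <- if (length(config$strata)) {
    run_stratified(analysis, config$strata, config$indices, config$age_cut)
  } else {
    NULL
  }

  association <- assemble_association_table(variants, strata)
  auc_table <- assemble_auc_table(variants, strata)

  sensitivity <- NULL
  if (config$imputation && nrow(excluded) > 0) {
    pooled <- run_imputed_sensitivity(
      harmonized[!is.na(harmonized$dementia), ],
      weights, m = config$m, seed = stage_seed(3), indices = config$indices
    )
    available <- index_specific_complete_case(
      harmonized[!is.na(harmonized$dementia), ], weights, config$indices
    )
    sensitivity <- list(pooled = pooled$pooled, available_case = available,
                        m = config$m, method = pooled$imputation$method)
  }

  flow <- tibble(
    stage = c("generated", "outcome_classified", "analytic_sample",
              "excluded_incomplete", "ad_analysis"),
    n = c(log$generated, sum(!is.na(harmonized$dementia)), nrow(analysis),
          log$generated - nrow(analysis),
          sum(!is.na(analysis$ad)))
  )

  report <- structure(
    list(config = config, flow = flow, descriptive = descriptive,
         association = association, auc = auc_table,
         sensitivity = sensitivity, variants = variants, strata = strata,
         analysis = analysis, log = log),
    class = "run_report"
  )
  check_report_consistency(report)
  if (!is.null(config$outdir)) write_report(report, config$outdir)
  report
}

assemble_association_table <- function(variants, strata) {
  block <- function(ev, label) {
    dplyr::mutate(ev$fits, block = label, .before = 1)
  }
  out <- list(
    block(variants$dementia, "Dementia"),
    block(variants$dementia_no_demographics, "Dementia No Demographics"),
    block(variants$ad, "AD"),
    block(variants$ad_no_demographics, "AD No Demographics")
  )
  if (!is.null(strata)) {
    for (axis in names(strata)) {
      for (s in names(strata[[axis]])) {
        out <- c(out, list(block(strata[[axis]][[s]], s)))
      }
    }
  }
  dplyr::bind_rows(out)
}

assemble_auc_table <- function(variants, strata) {
  block <- function(ev, label) {
    tab <- ev$roc$auc
    rc <- ev$roc$reference_contrasts
    stars <- stats::setNames(rc$stars, rc$model)
    tab$vs_reference <- ifelse(tab$model %in% names(stars),
                               stars[tab$model], "")
    dplyr::mutate(tab, block = label, n = ev$n, .before = 1)
  }
  out <- list(
    block(variants$dementia, "Dementia"),
    block(variants$dementia_no_demographics, "Dementia No Demographics"),
    block(variants$ad, "AD"),
    block(variants$ad_no_demographics, "AD No Demographics")
  )
  if (!is.null(strata)) {
    for (axis in names(strata)) {
      for (s in names(strata[[axis]])) {
        out <- c(out, list(block(strata[[axis]][[s]], s)))
      }
    }
  }
  dplyr::bind_rows(out)
}

# every percentage in the report must re-derive from counts in the report
check_report_consistency <- function(report) {
  d <- report$descriptive
  if (!is.null(d)) {
    tot <- stats::aggregate(n_included ~ factor, data = d, FUN = sum)
    tot_map <- stats::setNames(tot$n_included, tot$factor)
    redo <- as.numeric(fmt_pct(d$n_included, tot_map[d$factor]))
    if (any(abs(redo - d$pct_included) > 1e-9)) {
      stop("internal consistency failure: descriptive percentages do not re-derive")
    }
  }
  invisible(TRUE)
}

#' Write a run report to disk
#'
#' @param report a `run_report`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) {
    utils::write.table(x, file.path(dir, f), sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  wt(report$flow, "sample_flow.tsv")
  if (!is.null(report$descriptive)) wt(report$descriptive, "descriptive.tsv")
  wt(report$association, "association.tsv")
  wt(report$auc, "auc.tsv")
  if (!is.null(report$sensitivity)) {
    wt(report$sensitivity$pooled, "sensitivity_pooled.tsv")
    wt(report$sensitivity$available_case, "sensitivity_available_case.tsv")
  }
  cfg <- unclass(report$config)
  cfg$outdir <- NULL
  jsonlite::write_json(
    list(config = cfg, log = report$log),
    file.path(dir, "run_metadata.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("demrisk run report\n")
  cat("  analytic n:", x$log$analytic_n, "of", x$log$generated, "generated\n")
  cat("  association table:", nrow(x$association), "rows;",
      "AUC table:", nrow(x$auc), "rows\n")
  if (!is.null(x$sensitivity)) {
    cat("  sensitivity: m =", x$sensitivity$m, "imputations (",
        x$sensitivity$method, ")\n")
  }
  invisible(x)
}
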
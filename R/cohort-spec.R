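# YAML 1.1 reads bare yes/no as booleans; restore them as level strings
# (keys and scalar values) throughout a config tree.
fix_yaml_bools <- function(x) {
  if (is.list(x)) {
    if (!is.null(names(x))) {
      names(x) <- sub("^TRUE$", "yes", sub("^FALSE$", "no", names(x)))
    }
    return(lapply(x, fix_yaml_bools))
  }
  if (is.logical(x) && !all(is.na(x))) return(ifelse(x, "yes", "no"))
  x
}

default_cohort_config <- function() {
  fix_yaml_bools(yaml::read_yaml(demrisk_file("extdata", "cohort",
                                              "default_cohort.yaml")))
}

#' Specification of a synthetic cohort
#'
#' Bundles everything [generate_cohort()] needs: sample size, demographic
#' distribution, per-factor categorical prevalences (defaults derived from
#' the analytic-sample level counts shipped with the package), the latent
#' correlation structure of the Gaussian copula, the logistic outcome
#' model, and the MAR missingness model used by [inject_missingness()].
#'
#' @param n_participants number of participants (default: the analytic
#'   sample size of the calibration table, 5247).
#' @param seed integer seed; fixed seed gives byte-identical cohorts.
#' @param female_fraction proportion of women.
#' @param age_mean,age_sd baseline age distribution in years.
#' @param factor_prevalences named list (factor -> named probability
#'   vector over its levels) overriding the calibrated defaults.
#' @param latent_correlation either a full correlation matrix over
#'   `c("age", factors)` or a list of `(var1, var2, rho)` triples; unnamed
#'   pairs default to 0.
#' @param outcome_model list with `coefficients` (named: `age` per year,
#'   `education` per ordered level), `factor_effects` (factor ->
#'   `list(level=, beta=)` log-odds for carrying the named risk level), and
#'   either `intercept` or `target_prevalence` (intercept then calibrated on
#'   the realized linear predictor).
#' @param missingness_model per-variable MAR logistic models on age, sex
#'   and education; see [inject_missingness()].
#' @return a validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_participants = NULL, seed = 1L,
                        female_fraction = NULL, age_mean = NULL, age_sd = NULL,
                        factor_prevalences = NULL, latent_correlation = NULL,
                        outcome_model = NULL, missingness_model = NULL) {
  cfg <- default_cohort_config()
  prev <- lapply(cfg$counts_included[names(cfg$factor_levels)], function(cnt) {
    x <- unlist(cnt)
    x / sum(x)
  })
  names(prev) <- names(cfg$factor_levels)
  if (!is.null(factor_prevalences)) {
    for (f in names(factor_prevalences)) {
      p <- factor_prevalences[[f]]
      prev[[f]] <- p
    }
  }

  spec <- list(
    n_participants = n_participants %||% cfg$n_participants,
    seed = as.integer(seed),
    female_fraction = female_fraction %||% cfg$female_fraction,
    age_mean = age_mean %||% cfg$age_mean,
    age_sd = age_sd %||% cfg$age_sd,
    age_range = unlist(cfg$age_range),
    followup_offset = cfg$followup_offset_mean,
    factor_prevalences = prev,
    latent_correlation = build_latent_correlation(
      latent_correlation %||% cfg$latent_correlation, names(prev)
    ),
    outcome_model = outcome_model %||% cfg$outcome_model,
    ad_fraction = cfg$ad_fraction_of_dementia,
    mci_fractions = c(aMCI = cfg$mci_fraction_amnestic,
                      naMCI = cfg$mci_fraction_nonamnestic),
    apoe_homozygote_fraction = cfg$apoe_homozygote_fraction,
    missingness_model = missingness_model %||% cfg$missingness_model
  )
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

latent_variables <- function(factors) {
  c("age", setdiff(factors, composite_factors()), composite_factors())
}

build_latent_correlation <- function(corr, factors) {
  vars <- latent_variables(factors)
  if (is.matrix(corr)) {
    if (!identical(dim(corr), c(length(vars), length(vars)))) {
      stop("latent correlation matrix must be ", length(vars), " x ", length(vars))
    }
    dimnames(corr) <- list(vars, vars)
    return(corr)
  }
  R <- diag(length(vars))
  dimnames(R) <- list(vars, vars)
  for (pr in corr) {
    a <- pr[[1]]; b <- pr[[2]]; rho <- as.numeric(pr[[3]])
    if (!a %in% vars || !b %in% vars) {
      stop("latent correlation names unknown variable: ", a, " / ", b)
    }
    R[a, b] <- R[b, a] <- rho
  }
  R
}

validate_cohort_spec <- function(spec) {
  stopifnot(spec$n_participants >= 1)
  if (spec$female_fraction < 0 || spec$female_fraction > 1) {
    stop("female_fraction must be a proportion")
  }
  lev <- factor_levels()
  for (f in names(spec$factor_prevalences)) {
    p <- spec$factor_prevalences[[f]]
    if (any(p < 0) || any(p > 1)) stop("prevalences outside [0,1] for ", f)
    if (abs(sum(p) - 1) > 1e-6) stop("prevalences must sum to 1 for ", f)
    if (!is.null(lev[[f]]) && !setequal(names(p), lev[[f]])) {
      stop("prevalence levels do not match factor levels for ", f)
    }
    spec$factor_prevalences[[f]] <- p[lev[[f]]]
  }
  R <- spec$latent_correlation
  if (any(abs(R - t(R)) > 1e-10)) stop("latent correlation must be symmetric")
  if (any(abs(diag(R) - 1) > 1e-10)) stop("latent correlation must have unit diagonal")
  invisible(spec)
}
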
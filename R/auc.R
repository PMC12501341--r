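#' Rank-based AUC with DeLong confidence interval
#'
#' The area under the ROC curve computed as the Mann-Whitney probability
#' that a random case outranks a random control, with midrank handling of
#' ties; the variance is the DeLong placement-value (structural components)
#' estimator.
#'
#' @param pred numeric predicted risk (any monotone score).
#' @param outcome binary outcome (see [fit_logistic()] for codings).
#' @return list with `auc`, `var`, `ci` (95%, Wald, truncated to [0,1]),
#'   and `band` (interpretation label).
#' @export
auc_mw <- function(pred, outcome) {
  y <- to_binary(outcome)
  keep <- !is.na(pred) & !is.na(y)
  pred <- pred[keep]; y <- y[keep]
  if (length(unique(y)) < 2) stop("both outcome classes are required")
  pv <- placement_values(pred, y)
  a <- mean(pv$v10)
  v <- var(pv$v10) / length(pv$v10) + var(pv$v01) / length(pv$v01)
  ci <- pmin(1, pmax(0, a + c(-1, 1) * 1.96 * sqrt(v)))
  list(auc = a, var = v, ci = ci, band = interpretation_band(a))
}

# DeLong structural components: v10 per case, v01 per control
placement_values <- function(pred, y) {
  cases <- pred[y == 1]
  controls <- pred[y == 0]
  r <- rank(c(cases, controls), ties.method = "average")
  m <- length(cases); n <- length(controls)
  r1 <- r[seq_len(m)]
  r0 <- r[m + seq_len(n)]
  v10 <- (r1 - rank(cases, ties.method = "average")) / n
  v01 <- 1 - (r0 - rank(controls, ties.method = "average")) / m
  list(v10 = v10, v01 = v01)
}

#' AUC interpretation band
#'
#' Standard labels: 0.5-0.6 fail, 0.6-0.7 poor, 0.7-0.8 moderate,
#' 0.8-0.9 good, 0.9+ excellent (values below 0.5 are worse than chance).
#'
#' @param auc numeric vector of AUCs.
#' @return character vector of labels.
#' @export
interpretation_band <- function(auc) {
  labs <- c("worse than chance", "fail", "poor", "moderate", "good", "excellent")
  labs[findInterval(auc, c(0.5, 0.6, 0.7, 0.8, 0.9)) + 1L]
}

#' Compare correlated ROC curves (gated DeLong procedure)
#'
#' Estimates the joint covariance of several models' AUCs on the same
#' participants via DeLong placement values, then runs a global chi-square
#' test of AUC equality; pairwise z-tests are reported only when the global
#' test reaches the gate (p <= `gate_alpha`), which limits type-I error
#' inflation from multiple comparisons. Contrasts of every model against a
#' designated reference model are reported regardless of the gate, starred
#' at the 0.05 / 0.005 / 0.001 levels.
#'
#' @param predictions data frame or matrix of predicted risks, one column
#'   per model, on the identical participant set (rows with any missing
#'   prediction are an error, not silently dropped).
#' @param outcome binary outcome.
#' @param reference column name of the reference model (default none).
#' @param gate_alpha significance gate for pairwise testing.
#' @param global_models `"all"` (default): the global test spans every
#'   column including the reference; `"non_reference"`: indices only.
#' @return a `roc_comparison` list: `auc` tibble (model, auc, ci, band),
#'   `cov` (AUC covariance matrix), `global` (chi2, df, p), `pairwise`
#'   (tibble or NULL when gated closed), `reference_contrasts`, `n`.
#' @export
delong_compare <- function(predictions, outcome, reference = NULL,
                           gate_alpha = 0.05,
                           global_models = c("all", "non_reference")) {
  global_models <- match.arg(global_models)
  P <- as.matrix(predictions)
  if (anyNA(P)) stop("mismatched participant sets: missing predictions")
  y <- to_binary(outcome)
  if (anyNA(y)) stop("mismatched participant sets: missing outcomes")
  if (length(unique(y)) < 2) stop("both outcome classes are required")
  k <- ncol(P)
  models <- colnames(P) %||% paste0("model", seq_len(k))
  if (!is.null(reference) && !reference %in% models) {
    stop("reference model not among predictions: ", reference)
  }

  V10 <- sapply(seq_len(k), function(j) placement_values(P[, j], y)$v10)
  V01 <- sapply(seq_len(k), function(j) placement_values(P[, j], y)$v01)
  aucs <- colMeans(V10)
  S <- cov(V10) / nrow(V10) + cov(V01) / nrow(V01)
  dimnames(S) <- list(models, models)

  auc_tab <- tibble(
    model = models, auc = unname(aucs),
    se = sqrt(diag(S)),
    ci_low = pmax(0, unname(aucs) - 1.96 * sqrt(diag(S))),
    ci_high = pmin(1, unname(aucs) + 1.96 * sqrt(diag(S))),
    band = interpretation_band(unname(aucs))
  )

  glob_idx <- if (global_models == "non_reference" && !is.null(reference)) {
    which(models != reference)
  } else {
    seq_len(k)
  }
  global <- global_delong(aucs[glob_idx], S[glob_idx, glob_idx, drop = FALSE])

  pairwise <- NULL
  if (!is.na(global$p) && global$p <= gate_alpha) {
    pairs <- utils::combn(seq_len(k), 2)
    pairwise <- dplyr::bind_rows(apply(pairs, 2, function(ij) {
      i <- ij[1]; j <- ij[2]
      vd <- S[i, i] + S[j, j] - 2 * S[i, j]
      z <- if (vd <= 0) 0 else (aucs[i] - aucs[j]) / sqrt(vd)
      tibble(model1 = models[i], model2 = models[j],
             diff = aucs[i] - aucs[j], z = z, p = 2 * pnorm(-abs(z)))
    }))
    pairwise$stars <- star_flags(pairwise$p)
  }

  reference_contrasts <- NULL
  if (!is.null(reference)) {
    r <- which(models == reference)
    others <- setdiff(seq_len(k), r)
    reference_contrasts <- dplyr::bind_rows(lapply(others, function(i) {
      vd <- S[i, i] + S[r, r] - 2 * S[i, r]
      z <- if (vd <= 0) 0 else (aucs[i] - aucs[r]) / sqrt(vd)
      tibble(model = models[i], reference = reference,
             diff = aucs[i] - aucs[r], z = z, p = 2 * pnorm(-abs(z)))
    }))
    reference_contrasts$stars <- star_flags(reference_contrasts$p)
  }

  structure(
    list(auc = auc_tab, cov = S, global = global, pairwise = pairwise,
         reference_contrasts = reference_contrasts,
         gate_alpha = gate_alpha, n = length(y)),
    class = "roc_comparison"
  )
}

# quadratic-form chi-square test of AUC equality over a set of models
global_delong <- function(aucs, S) {
  k <- length(aucs)
  if (k < 2) return(list(chi2 = NA_real_, df = 0L, p = NA_real_))
  L <- cbind(-1, diag(k - 1))          # contrasts vs the first model
  d <- drop(L %*% aucs)
  V <- L %*% S %*% t(L)
  Vi <- tryCatch(solve(V), error = function(e) MASS::ginv(V))
  chi2 <- drop(t(d) %*% Vi %*% d)
  df <- qr(V)$rank
  if (max(abs(d)) < 1e-14) return(list(chi2 = 0, df = as.integer(df), p = 1))
  list(chi2 = chi2, df = as.integer(df),
       p = pchisq(chi2, df, lower.tail = FALSE))
}

#' @export
print.roc_comparison <- function(x, ...) {
  cat("ROC comparison on n =", x$n, "participants\n")
  print(x$auc, ...)
  cat(sprintf("Global DeLong test: chi2 = %.3f, df = %d, p = %.4g\n",
              x$global$chi2, x$global$df, x$global$p))
  if (is.null(x$pairwise)) {
    cat("Pairwise comparisons withheld (global gate not passed)\n")
  } else {
    print(x$pairwise, ...)
  }
  invisible(x)
}
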
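#' Z-standardize a numeric vector
#'
#' Centers to mean 0 and scales to SD 1 (denominator n-1), returning the
#' transform parameters so the same scale can be reused on strata.
#'
#' @param x numeric vector (at least two distinct values).
#' @param center,scale optionally reuse previously estimated parameters.
#' @return list with `z`, `mean`, `sd`.
#' @export
zstandardize <- function(x, center = NULL, scale = NULL) {
  if (is.null(center)) center <- mean(x, na.rm = TRUE)
  if (is.null(scale)) scale <- sd(x, na.rm = TRUE)
  if (is.na(scale) || scale == 0) stop("cannot z-standardize a constant input")
  list(z = (x - center) / scale, mean = center, sd = scale)
}

#' Fit a logistic regression model
#'
#' Maximum-likelihood logistic fit with Wald 95% confidence intervals,
#' odds ratios, and McFadden pseudo R-squared (1 - logLik/logLik0).
#' Quasi-complete separation is flagged (and, on request, a ridge-penalized
#' refit via iterated weighted least squares is reported instead of the
#' diverging ML estimates).
#'
#' @param outcome binary outcome: logical, 0/1, or a two-level factor
#'   (second level = event).
#' @param covariates data frame of numeric covariates.
#' @param model_id label stored in the result.
#' @param penalize_on_separation refit with a small L2 penalty when
#'   separation is detected.
#' @return a `demrisk_fit` list: `tidy` tibble (term, estimate, se, or,
#'   ci_low, ci_high, p), `pseudo_r2`, `n`, `loglik`, `aic`, `chi2`
#'   (likelihood-ratio statistic vs the null model), `converged`,
#'   `separation`, and `fitted` (event probabilities).
#' @export
fit_logistic <- function(outcome, covariates, model_id = "model",
                         penalize_on_separation = FALSE) {
  y <- to_binary(outcome)
  df <- as.data.frame(covariates)
  keep <- !is.na(y) & stats::complete.cases(df)
  y <- y[keep]
  df <- df[keep, , drop = FALSE]
  if (length(unique(y)) < 2) stop("outcome has a single class")

  fit <- glm(y ~ ., data = df, family = binomial())
  separation <- any(abs(coef(fit)[-1]) > 15, na.rm = TRUE) ||
    max(fit$fitted.values) > 1 - 1e-10 || min(fit$fitted.values) < 1e-10
  if (separation) {
    warning("possible quasi-complete separation in model '", model_id, "'",
            if (penalize_on_separation) "; reporting ridge-penalized refit")
    if (penalize_on_separation) fit <- ridge_logistic(y, df)
  }

  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  ll <- as.numeric(logLik(fit))
  null_fit <- glm(y ~ 1, family = binomial())
  ll0 <- as.numeric(logLik(null_fit))
  z <- est / se
  tidy <- tibble(
    model = model_id,
    term = names(est),
    estimate = unname(est),
    se = unname(se),
    or = exp(unname(est)),
    ci_low = exp(unname(est - 1.96 * se)),
    ci_high = exp(unname(est + 1.96 * se)),
    p = 2 * pnorm(-abs(unname(z)))
  )
  structure(
    list(
      model_id = model_id, tidy = tidy,
      pseudo_r2 = max(0, 1 - ll / ll0),
      n = length(y), loglik = ll, null_loglik = ll0,
      aic = stats::AIC(fit),
      chi2 = 2 * (ll - ll0),
      chi2_p = pchisq(2 * (ll - ll0), df = length(est) - 1, lower.tail = FALSE),
      converged = fit$converged %||% TRUE,
      separation = separation,
      fitted = unname(predict(fit, newdata = df, type = "response"))
    ),
    class = "demrisk_fit"
  )
}

to_binary <- function(outcome) {
  if (is.logical(outcome)) return(as.integer(outcome))
  if (is.factor(outcome) || is.character(outcome)) {
    f <- as.factor(outcome)
    if (nlevels(f) > 2) stop("outcome must have two levels")
    return(as.integer(f) - 1L)
  }
  as.integer(outcome)
}

# minimal ridge-penalized logistic (IRLS with fixed small lambda); keeps the
# package self-contained for the rare separated stratum
ridge_logistic <- function(y, df, lambda = 1e-2, maxit = 100) {
  X <- cbind(`(Intercept)` = 1, as.matrix(df))
  beta <- rep(0, ncol(X))
  P <- diag(c(0, rep(lambda, ncol(X) - 1)))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- invlogit(eta)
    W <- mu * (1 - mu)
    H <- crossprod(X, X * W) + P
    g <- crossprod(X, y - mu) - P %*% beta
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < 1e-8) break
  }
  eta <- drop(X %*% beta)
  mu <- invlogit(eta)
  V <- solve(crossprod(X, X * (mu * (1 - mu))) + P)
  structure(
    list(coefficients = stats::setNames(drop(beta), colnames(X)),
         fitted.values = mu, converged = TRUE,
         penalized = TRUE, X = X, y = y, vcov_mat = V),
    class = "demrisk_ridge"
  )
}

#' @export
coef.demrisk_ridge <- function(object, ...) object$coefficients
#' @export
vcov.demrisk_ridge <- function(object, ...) object$vcov_mat
#' @export
logLik.demrisk_ridge <- function(object, ...) {
  mu <- object$fitted.values
  structure(sum(object$y * log(mu) + (1 - object$y) * log(1 - mu)),
            df = length(object$coefficients), class = "logLik")
}
#' @export
predict.demrisk_ridge <- function(object, newdata = NULL, type = "response", ...) {
  object$fitted.values
}

#' @export
AIC.demrisk_ridge <- function(object, ..., k = 2) {
  -2 * as.numeric(logLik(object)) + k * length(object$coefficients)
}
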
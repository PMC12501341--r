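test_that("z-standardization centers, scales with n-1, and errors on constants", {
  z <- zstandardize(c(1, 2, 3))
  expect_equal(z$z, c(-1, 0, 1))
  x <- c(2, 4, 4, 4, 5, 5, 7, 9)
  zx <- zstandardize(x)
  expect_lt(abs(mean(zx$z)), 1e-12)
  expect_equal(sd(zx$z), 1)
  expect_equal(zx$z[8], (9 - 5) / sqrt(32 / 7))  # hand-computed n-1 SD
  expect_error(zstandardize(rep(3, 5)), "constant")
  # parameter reuse for strata
  z2 <- zstandardize(c(10, 20), center = zx$mean, scale = zx$sd)
  expect_equal(z2$z, (c(10, 20) - 5) / sqrt(32 / 7))
})

test_that("logistic fit on collapsed 2x2 data equals the cross-product odds ratio", {
  # a=30 exposed cases, b=70 exposed controls, c=15, d=185
  x <- c(rep(1, 100), rep(0, 200))
  y <- c(rep(1, 30), rep(0, 70), rep(1, 15), rep(0, 185))
  f <- fit_logistic(y, data.frame(x = x))
  or_hat <- f$tidy$or[f$tidy$term == "x"]
  expect_equal(or_hat, (30 * 185) / (70 * 15), tolerance = 1e-6)
})

test_that("a covariate independent of the outcome gives OR ~ 1 and pseudo-R2 ~ 0", {
  set.seed(8)
  n <- 20000
  x <- rnorm(n)
  y <- rbinom(n, 1, 0.2)
  f <- fit_logistic(y, data.frame(x = x))
  expect_lt(abs(log(f$tidy$or[2])), 0.05)
  expect_lt(f$pseudo_r2, 0.001)
})

test_that("quasi-complete separation is flagged and the ridge refit is finite", {
  x <- c(rep(0, 20), rep(1, 20))
  y <- c(rep(0, 20), rep(1, 20))
  expect_warning(f <- fit_logistic(y, data.frame(x = x)), "separation")
  expect_true(f$separation)
  expect_warning(
    g <- fit_logistic(y, data.frame(x = x), penalize_on_separation = TRUE),
    "separation"
  )
  expect_true(all(is.finite(g$tidy$estimate)))
})

test_that("rank AUC handles the canonical separable and tied cases", {
  expect_equal(auc_mw(c(1, 2, 10, 11), c(0, 0, 1, 1))$auc, 1)
  expect_equal(auc_mw(rep(1, 10), rep(0:1, 5))$auc, 0.5)
  # cases (3, 5) vs controls (1, 4): pairs 3>1, 3<4, 5>1, 5>4 -> 3/4
  expect_equal(auc_mw(c(3, 5, 1, 4), c(1, 1, 0, 0))$auc,
               oracle_auc(c(3, 5, 1, 4), c(1, 1, 0, 0)))
  expect_equal(auc_mw(c(3, 5, 1, 4), c(1, 1, 0, 0))$auc, 0.75)
  expect_error(auc_mw(1:4, rep(1, 4)), "both outcome classes")
})

test_that("rank AUC equals the exhaustive pair-count oracle on random tied data", {
  set.seed(15)
  for (i in 1:200) {
    n <- sample(4:12, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    pred <- sample(1:4, n, replace = TRUE)  # heavy ties on purpose
    expect_equal(auc_mw(pred, y)$auc, oracle_auc(pred, y), tolerance = 1e-12)
  }
})

test_that("AUC is invariant to monotone transformation through the logistic model", {
  set.seed(16)
  n <- 800
  x <- rnorm(n)
  y <- rbinom(n, 1, invlogit(-1 + x))
  f <- fit_logistic(y, data.frame(x = x))
  expect_equal(auc_mw(f$fitted, y)$auc, auc_mw(x, y)$auc)
})

test_that("OR per SD is invariant to affine rescaling of the raw score", {
  set.seed(17)
  n <- 2000
  s <- rnorm(n, 50, 10)
  y <- rbinom(n, 1, invlogit(-3 + 0.05 * s))
  f1 <- fit_logistic(y, data.frame(z = zstandardize(s)$z))
  f2 <- fit_logistic(y, data.frame(z = zstandardize(7 * s - 200)$z))
  expect_equal(f1$tidy$or[2], f2$tidy$or[2], tolerance = 1e-8)
})

test_that("comparing a model to itself yields zero difference and p = 1", {
  set.seed(18)
  pred <- rnorm(100)
  y <- rbinom(100, 1, 0.5)
  rc <- delong_compare(data.frame(a = pred, b = pred), y)
  expect_equal(rc$global$p, 1)
  expect_equal(diff(rc$auc$auc), 0)
})

test_that("with two models the global chi-square equals the squared pairwise z", {
  set.seed(19)
  n <- 300
  y <- rbinom(n, 1, 0.4)
  p1 <- rnorm(n) + y
  p2 <- rnorm(n) + 0.5 * y
  rc <- delong_compare(data.frame(m1 = p1, m2 = p2), y, gate_alpha = 1)
  expect_false(is.null(rc$pairwise))
  expect_equal(rc$global$chi2, rc$pairwise$z[1]^2, tolerance = 1e-9)
})

test_that("DeLong AUC variance and paired test agree with pROC", {
  skip_if_not_installed("pROC")
  set.seed(20)
  n <- 400
  y <- rbinom(n, 1, 0.35)
  p1 <- rnorm(n) + 1.2 * y
  p2 <- rnorm(n) + 0.8 * y
  rc <- delong_compare(data.frame(m1 = p1, m2 = p2), y,
                       reference = "m2", gate_alpha = 1)
  r1 <- pROC::roc(y, p1, quiet = TRUE, direction = "<")
  expect_equal(rc$auc$auc[1], as.numeric(pROC::auc(r1)))
  expect_equal(unname(rc$auc$se[1]^2),
               as.numeric(pROC::var(r1, method = "delong")),
               tolerance = 1e-10)
  pt <- pROC::roc.test(r1, pROC::roc(y, p2, quiet = TRUE, direction = "<"),
                       method = "delong", paired = TRUE)
  expect_equal(rc$reference_contrasts$p[1], as.numeric(pt$p.value),
               tolerance = 1e-10)
})

test_that("the pairwise table is withheld when the global gate stays closed", {
  set.seed(21)
  n <- 500
  y <- rbinom(n, 1, 0.5)
  # two exchangeable noise models: the gate should almost surely stay shut
  rc <- delong_compare(data.frame(a = rnorm(n), b = rnorm(n)), y,
                       gate_alpha = 1e-12)
  expect_null(rc$pairwise)
  expect_error(delong_compare(data.frame(a = c(NA, rnorm(n - 1)), b = rnorm(n)), y),
               "mismatched")
})

test_that("AUC interpretation bands follow the standard thresholds", {
  expect_equal(interpretation_band(c(0.55, 0.65, 0.75, 0.85, 0.95)),
               c("fail", "poor", "moderate", "good", "excellent"))
})

test_that("evaluation variants share the sample and AD drops non-AD dementia", {
  spec <- cohort_spec(n_participants = 2500, seed = 55)
  h <- harmonize_cohort(generate_cohort(spec))
  an <- build_analysis_set(h, WT)
  res <- run_outcome_variants(an)
  expect_equal(res$dementia$n, nrow(an))
  n_other <- sum(an$dementia == 1 & is.na(an$ad))
  expect_equal(res$ad$n, nrow(an) - n_other)
  expect_gt(n_other, 0)
  # without-demographics scores differ from the with-demographics ones
  expect_false(isTRUE(all.equal(res$dementia$roc$auc$auc,
                                res$dementia_no_demographics$roc$auc$auc)))
  # shaped like the published table: five indices plus the reference
  expect_equal(nrow(res$dementia$roc$auc), 6)
})

test_that("stratified analyses partition the sample and reuse cohort z-parameters", {
  spec <- cohort_spec(n_participants = 3000, seed = 56)
  h <- harmonize_cohort(generate_cohort(spec))
  an <- build_analysis_set(h, WT)
  st <- run_stratified(an, axes = c("sex", "apoe4"))
  expect_equal(st$sex$Female$n + st$sex$Male$n, nrow(an))
  expect_equal(st$apoe4$`APOE4 Negative`$n + st$apoe4$`APOE4 Positive`$n,
               nrow(an))
  # degenerate single-stratum axis reproduces the unstratified fits
  one <- evaluate_cohort(an, "dementia", TRUE)
  again <- evaluate_cohort(an, "dementia", TRUE, z_params = one$z_params)
  expect_equal(one$fits$or, again$fits$or)
})
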
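mcar_data <- function(n = 120, effect = -0.4, miss = 0.2, seed = NULL) {
  d <- sim_z_data(n = n, effect = effect, seed = seed)
  d$bmi <- rnorm(n, 36, 5)
  d$z_full <- d$z
  d$z[sample(n, round(miss * n))] <- NA
  d
}

test_that("imputation is a no-op on complete data and reproducible by seed", {
  d <- sim_z_data(n = 60, seed = 61)
  imp <- mice_impute(d, imputable = "z", predictors = c("z0", "imd_band"),
                     m = 2, seed = 1)
  expect_identical(imp[[1]], d)
  expect_identical(imp[[2]], d)

  d <- mcar_data(seed = 62)
  a <- mice_impute(d, imputable = "z", predictors = c("z0", "bmi", "imd_band"),
                   m = 3, seed = 7)
  b <- mice_impute(d, imputable = "z", predictors = c("z0", "bmi", "imd_band"),
                   m = 3, seed = 7)
  expect_identical(a, b)
  # observed cells never overwritten
  obs <- !is.na(d$z)
  for (k in 1:3) expect_identical(a[[k]]$z[obs], d$z[obs])
  # imputed cells filled
  for (k in 1:3) expect_false(anyNA(a[[k]]$z))
})

test_that("imputation handles categorical columns and arm separation", {
  d <- mcar_data(seed = 63)
  d$education <- sample(c("secondary", "college", "degree"), nrow(d), TRUE)
  d$employed <- sample(c("yes", "no"), nrow(d), TRUE)
  d$education[sample(nrow(d), 15)] <- NA
  d$employed[sample(nrow(d), 15)] <- NA
  imp <- mice_impute(d, imputable = c("z", "education", "employed"),
                     predictors = c("z0", "bmi"), m = 2, seed = 8)
  expect_false(anyNA(imp[[1]][c("z", "education", "employed")]))
  expect_true(all(imp[[1]]$education %in% c("secondary", "college", "degree")))
  # a column fully missing within one arm is unimputable
  d2 <- sim_z_data(n = 40, seed = 64)
  d2$z[d2$arm == "intervention"] <- NA
  expect_error(mice_impute(d2, imputable = "z", predictors = "z0", m = 2),
               "fully missing")
  # undeclared missingness is refused
  d3 <- sim_z_data(n = 40, seed = 65)
  d3$z0[1] <- NA
  expect_error(mice_impute(d3, imputable = "z", predictors = "z0", m = 2),
               "outside declared")
})

test_that("rubin pooling matches the hand-worked example", {
  p <- pool_rubin(c(-0.3, -0.5), sqrt(c(0.01, 0.01)))
  expect_equal(p$estimate, -0.4)
  expect_equal(p$between_var, 0.02)
  expect_equal(p$total_var, 0.01 + 1.5 * 0.02)
  expect_equal(p$se, sqrt(0.04))
})

test_that("rubin pooling collapses to the single fit when imputations agree", {
  est <- rep(-0.42, 5); se <- rep(0.11, 5)
  p <- pool_rubin(est, se)
  expect_equal(p$estimate, -0.42)
  expect_equal(p$between_var, 0)
  expect_equal(p$se, 0.11)
  expect_equal(p$ci_low, -0.42 - qnorm(0.975) * 0.11)
  expect_error(pool_rubin(-0.3, 0.1), "m >= 2")
})

test_that("pooled variance never falls below the mean within-imputation variance", {
  set.seed(66)
  for (i in 1:10) {
    est <- rnorm(10, -0.3, 0.05); se <- runif(10, 0.08, 0.12)
    p <- pool_rubin(est, se)
    expect_gte(p$total_var, p$within_var)
    # CI at least as wide as the mean within-imputation (normal) CI
    expect_gte(p$ci_high - p$ci_low, 2 * qnorm(0.975) * sqrt(mean(se^2)) - 1e-12)
  }
})

test_that("barnard-rubin df shrink below the complete-data df", {
  p <- pool_rubin(c(-0.3, -0.45, -0.5), c(0.1, 0.11, 0.1), df_complete = 100)
  expect_lt(p$df, 100)
  expect_gt(p$df, 0)
})

test_that("pooled ancova under MCAR tracks the full-data effect (scaled run)", {
  # scaled-down version of the 200-replicate acceptance check
  set.seed(67)
  diffs <- replicate(30, {
    d <- mcar_data(n = 120, effect = -0.4, miss = 0.2)
    full <- ancova_effect(transform(d, z = z_full), "z", "z0")$estimate
    imp <- mice_impute(d[setdiff(names(d), "z_full")], imputable = "z",
                       predictors = c("z0", "bmi", default_covariates_for_test()),
                       m = 3)
    pooled <- pooled_ancova(imp, outcome = "z", baseline = "z0")$estimate
    pooled - full
  })
  expect_lt(abs(mean(diffs)), 0.1)
})

test_that("ipw with universal follow-up equals the unweighted ancova", {
  d <- sim_z_data(n = 80, effect = -0.4, seed = 68)
  d$followed <- 1L
  eff_w <- ipw_effect(d, "followed", predictors = "imd_band",
                      outcome = "z", baseline = "z0")
  eff_u <- ancova_effect(d, "z", "z0")
  expect_equal(eff_w$estimate, eff_u$estimate, tolerance = 1e-8)
  expect_equal(eff_w$se, eff_u$se, tolerance = 1e-8)
  # constant weights are equivalent to no weights
  eff_c <- ancova_effect(d, "z", "z0", weights = rep(2, 80))
  expect_equal(eff_c$estimate, eff_u$estimate, tolerance = 1e-12)
  expect_equal(eff_c$se, eff_u$se, tolerance = 1e-10)
})

test_that("low follow-up probabilities are floored and logged", {
  set.seed(69)
  n <- 400
  d <- sim_z_data(n = n)
  # follow-up driven hard by a binary indicator: some fitted p below 0.02
  d$frail <- rep(c(1, 0), c(80, n - 80))
  d$followed <- ifelse(d$frail == 1, rbinom(n, 1, 0.01), rbinom(n, 1, 0.95))
  eff <- ipw_effect(d, "followed", predictors = "frail",
                    outcome = "z", baseline = "z0")
  expect_gt(attr(eff, "n_truncated"), 0)
  expect_lte(max(attr(eff, "weights")), 1 / 0.02)
  expect_error(ipw_effect(transform(d, followed = followed + 1), "followed",
                          "frail", "z", "z0"), "0/1")
})

test_that("ipw corrects arm-by-deprivation MAR dropout (scaled run)", {
  # dropout concentrated among deprived intervention participants, outcome
  # shifted by deprivation; the crude complete-case model omits imd_band
  set.seed(70)
  res <- replicate(40, {
    d <- sim_z_data(n = 400, effect = -0.4, imd_shift = 0.8)
    p_fu <- ifelse(d$arm == "intervention" & d$imd_band == "1-5", 0.35, 0.95)
    d$followed <- rbinom(400, 1, p_fu)
    cc <- ancova_effect(d[d$followed == 1, ], "z", "z0", covariates = character(0))
    ipw <- ipw_effect(d, "followed", predictors = c("arm", "imd_band"),
                      outcome = "z", baseline = "z0", covariates = character(0))
    c(cc = cc$estimate, ipw = ipw$estimate)
  })
  bias_cc <- abs(mean(res["cc", ]) + 0.4)
  bias_ipw <- abs(mean(res["ipw", ]) + 0.4)
  expect_lt(bias_ipw, bias_cc)
  expect_gt(mean(abs(res["ipw", ] + 0.4) < abs(res["cc", ] + 0.4)), 0.6)
})

test_that("weight-change interaction analysis reports both models", {
  set.seed(71)
  n <- 200
  d <- sim_z_data(n = n, effect = -0.3)
  d$weight_change <- ifelse(d$arm == "intervention", rnorm(n, -9, 4), rnorm(n, -1, 3))
  res <- weight_interaction(d, "z", "z0", covariates = character(0))
  expect_true(all(c("no_interaction", "interaction") %in% names(res)))
  expect_true(is.finite(res$interaction$p_value))
  # degenerate: constant weight change
  d$weight_change <- 0
  expect_error(weight_interaction(d, "z", "z0", covariates = character(0)),
               "inestimable|constant")
})

test_that("a true group-by-weight-change interaction is detected (scaled run)", {
  set.seed(72)
  hits <- replicate(40, {
    n <- 234
    d <- sim_z_data(n = n)
    d$weight_change <- ifelse(d$arm == "intervention", rnorm(n, -9, 5), rnorm(n, -1, 3))
    # effect proportional to weight lost in the intervention arm; the slope
    # is chosen so the positive control itself has adequate power
    d$z <- d$z + 0.12 * d$weight_change * (d$arm == "intervention")
    weight_interaction(d, "z", "z0", covariates = character(0))$interaction$p_value < 0.05
  })
  expect_gt(mean(hits), 0.8)
})

test_that("a weight-independent effect shows no interaction signal", {
  set.seed(73)
  pvals <- replicate(60, {
    d <- sim_z_data(n = 150, effect = -0.4)
    d$weight_change <- rnorm(150, -5, 5)
    weight_interaction(d, "z", "z0", covariates = character(0))$interaction$p_value
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})
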
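test_that("a noiseless additive group effect is recovered exactly", {
  set.seed(51)
  n <- 40
  d <- data.frame(arm = rep(c("control", "intervention"), n / 2),
                  z0 = rnorm(n))
  d$z <- 0.3 * d$z0 + ifelse(d$arm == "intervention", -0.5, 0)
  eff <- ancova_effect(d, "z", "z0", covariates = character(0))
  expect_equal(eff$estimate, -0.5, tolerance = 1e-12)
  expect_equal(eff$ci_high - eff$ci_low, 0, tolerance = 1e-10)
  expect_equal(eff$n_analyzed, n)
})

test_that("ancova matches an independent normal-equations oracle", {
  # balanced n = 20 fixture (every factor level occupied twice, so no
  # sparse-level merging happens and the design is known exactly)
  set.seed(52)
  d <- data.frame(
    arm = sample(rep(c("control", "intervention"), 10)),
    sex = sample(rep(c("female", "male"), c(14, 6))),
    age_band = sample(rep(c("<50", "50+"), c(12, 8))),
    imd_band = sample(rep(c("1-5", "6-10"), 10)),
    ethnicity = sample(rep(c("south_asian", "white"), c(4, 16))),
    chosen_symptom = sample(rep(c("fatigue", "breathlessness", "pain"), c(10, 5, 5))),
    z0 = rnorm(20))
  d$z <- -0.4 * (d$arm == "intervention") + 0.5 * d$z0 + rnorm(20)
  eff <- ancova_effect(d, "z", "z0")
  # oracle: explicit design matrix and normal equations, built separately
  X <- model.matrix(~ factor(arm, c("control", "intervention")) + z0 +
                      factor(age_band) + factor(imd_band) + factor(sex) +
                      factor(ethnicity == "south_asian") +
                      factor(chosen_symptom), data = d)
  beta <- solve(crossprod(X), crossprod(X, d$z))
  expect_equal(eff$estimate, as.numeric(beta[2, 1]), tolerance = 1e-8)
  resid <- d$z - X %*% beta
  s2 <- sum(resid^2) / (nrow(X) - ncol(X))
  se <- sqrt(s2 * solve(crossprod(X))[2, 2])
  expect_equal(eff$se, se, tolerance = 1e-8)
  expect_equal(eff$df, nrow(X) - ncol(X))
})

test_that("degenerate designs fail loudly", {
  d <- sim_z_data(n = 30, seed = 53)
  d$dup <- d$z0
  expect_error(ancova_effect(d, "z", "z0", covariates = "dup"), "collinear|dup")
  expect_error(ancova_effect(d[0, ], "z", "z0"), "no complete")
  d$arm <- "control"
  expect_error(ancova_effect(d, "z", "z0"), "both arms")
})

test_that("sparse covariate levels are merged, single-level covariates dropped", {
  d <- sim_z_data(n = 60, seed = 54)
  d$sex[1] <- "other"            # single participant
  d$ethnicity <- "white"         # single level
  expect_silent(eff <- ancova_effect(d, "z", "z0"))
  expect_true(is.finite(eff$estimate))
})

test_that("mixed model collapses to ancova with one row per participant", {
  d <- sim_z_data(n = 80, effect = -0.5, seed = 55)
  long <- data.frame(participant_id = d$participant_id, arm = d$arm,
                     vas = d$z, vas_baseline = d$z0,
                     d[c("age_band", "imd_band", "sex", "ethnicity", "chosen_symptom")])
  m <- mixed_other_effect(long)
  a <- ancova_effect(long, "vas", "vas_baseline")
  expect_equal(m$estimate, a$estimate, tolerance = 1e-6)
  expect_equal(m$se, a$se, tolerance = 1e-6)
  expect_identical(attr(m, "model"), "ols_fallback")
})

test_that("mixed model recovers a group effect on repeated ratings", {
  # between-participant s.d. 1, within 0.5, effect -0.8; scaled-down
  # replicate count relative to the full calibration (runtime)
  set.seed(56)
  est <- replicate(60, {
    n <- 180
    id <- rep(seq_len(n), each = 3)
    arm <- rep(rep(c("control", "intervention"), n / 2), each = 3)
    u <- rep(rnorm(n, sd = 1), each = 3)
    base <- rep(rnorm(n, 6, 1.5), each = 3)
    vas <- 5 + 0.4 * base + u - 0.8 * (arm == "intervention") + rnorm(3 * n, sd = 0.5)
    long <- data.frame(participant_id = id, arm = arm, vas = vas,
                       vas_baseline = base)
    mixed_other_effect(long, covariates = character(0))$estimate
  })
  expect_equal(mean(est), -0.8, tolerance = 0.1)
})

test_that("zero within-participant variance puts the random effect at the boundary", {
  set.seed(57)
  n <- 40
  id <- rep(seq_len(n), each = 2)
  arm <- rep(rep(c("control", "intervention"), n / 2), each = 2)
  base <- rep(rnorm(n, 6, 1), each = 2)
  vas <- 4 + 0.5 * base - 0.6 * (arm == "intervention") + rep(rnorm(n, sd = 1), each = 2)
  long <- data.frame(participant_id = id, arm = arm, vas = vas, vas_baseline = base)
  m <- mixed_other_effect(long, covariates = character(0))
  expect_true(is.finite(m$estimate))
  vc <- as.data.frame(lme4::VarCorr(attr(m, "fit")))
  expect_lt(vc$vcov[vc$grp == "Residual"], 1e-6)
})

test_that("subgroup forest reports per-level effects and interaction p", {
  d <- sim_z_data(n = 200, effect = -0.5, seed = 58)
  d$bmi <- rnorm(200, 36, 5)
  d$age <- rnorm(200, 46, 10)
  res <- subgroup_forest(d, "z", "z0", variables = c("sex", "imd_band", "bmi"))
  expect_setequal(unique(res$variable), c("sex", "imd_band", "bmi"))
  expect_equal(sort(res$level[res$variable == "bmi"]), c("T1", "T2", "T3"))
  expect_equal(length(unique(res$interaction_p[res$variable == "sex"])), 1L)
  d$onelevel <- "a"
  expect_warning(subgroup_forest(d, "z", "z0", variables = "onelevel"), "single level")
})

test_that("a sex-restricted effect is flagged by the interaction test", {
  # effect -0.7 s.d. in females only, balanced sexes (power requires it)
  set.seed(59)
  hits <- replicate(80, {
    d <- sim_z_data(n = 234)
    d$sex <- rep(c("female", "female", "male", "male"), length.out = 234)
    d$z <- d$z0 * 0.5 + sqrt(0.75) * rnorm(234) -
      0.7 * (d$arm == "intervention" & d$sex == "female")
    res <- subgroup_forest(d, "z", "z0", variables = "sex",
                           covariates = c("imd_band", "sex"))
    res$interaction_p[1] < 0.05
  })
  expect_gt(mean(hits), 0.8)
})

test_that("sample size solver reproduces the design values", {
  expect_identical(sample_size_t(0.5, power = 0.90, alpha = 0.05), 86L)
  # monotone shrinkage with effect size
  n1 <- sample_size_t(1.0, power = 0.90, alpha = 0.05)
  expect_lt(n1, 86 / 2 + 1)
  # normal-approximation lower bound: 2(z_.975 + z_.9)^2 / 0.5^2 = 84.06
  expect_gte(sample_size_t(0.5, power = 0.90), 85)
  expect_error(sample_size_t(0, power = 0.9), "delta")
})

test_that("noncentral-t power behaves and round-trips with the solver", {
  expect_equal(power_t(0.5, 97, 117), 0.952, tolerance = 5e-4)
  expect_equal(power_t(0, 10, 10), 0.05, tolerance = 1e-10)
  expect_gte(power_t(0.5, 86, 86), 0.90)
  # monotone in n and |delta|
  expect_gt(power_t(0.5, 100, 117), power_t(0.5, 97, 117))
  expect_gt(power_t(0.5, 97, 120), power_t(0.5, 97, 117))
  expect_gt(power_t(0.6, 97, 117), power_t(0.5, 97, 117))
  for (pow in c(0.8, 0.9)) {
    n <- sample_size_t(0.5, power = pow)
    expect_gte(power_t(0.5, n, n), pow)
    expect_lt(power_t(0.5, n - 1, n - 1), pow)
  }
})

test_that("QALY area under the utility curve is the trapezoid rule", {
  expect_equal(qaly_auc(c(1, 1), c(0, 6)), 0.5)
  expect_equal(qaly_auc(c(0.6, 0.8), c(0, 6)), 0.35)
  expect_error(qaly_auc(0.7, 0), ">= 2")
  expect_error(qaly_auc(c(0.7, 0.8), c(6, 0)), "increasing")
  # linear in utilities and additive over adjacent intervals
  u1 <- c(0.5, 0.7, 0.9); u2 <- c(0.2, 0.1, 0.4); tm <- c(0, 3, 6)
  expect_equal(qaly_auc(2 * u1 + 3 * u2, tm),
               2 * qaly_auc(u1, tm) + 3 * qaly_auc(u2, tm))
  expect_equal(qaly_auc(u1, tm),
               qaly_auc(u1[1:2], tm[1:2]) + qaly_auc(u1[2:3], tm[2:3]))
})

test_that("productivity change summarizes and adjusts as constructed", {
  d <- data.frame(arm = rep(c("control", "intervention"), each = 10),
                  hours_baseline = rep(10, 20), hours_followup = rep(10, 20))
  res <- productivity_change(d, covariates = character(0))
  expect_equal(res$summary$mean_change, c(0, 0))
  expect_equal(res$effect$estimate, 0)
  # noiseless -3h intervention vs -2h control: adjusted difference -1
  d$hours_followup <- d$hours_baseline + ifelse(d$arm == "intervention", -3, -2)
  res <- productivity_change(d, covariates = character(0))
  expect_equal(abs(res$effect$estimate), 1, tolerance = 1e-12)
  # missing follow-up excluded and counted
  d$hours_followup[1] <- NA
  res <- productivity_change(d, covariates = character(0))
  expect_equal(res$n_missing, 1)
  expect_equal(res$effect$n_analyzed, 19)
  d$hours_baseline[2] <- -1
  expect_error(productivity_change(d), "negative")
})
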
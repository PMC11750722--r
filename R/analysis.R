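# ---------------------------------------------------------------------------
# Treatment-effect estimation. The primary analysis is baseline-adjusted
# linear regression (ANCOVA): follow-up outcome on a binary arm indicator,
# the five stratification variables and the baseline value of the outcome,
# complete cases only, no multiplicity adjustment. CIs and p-values use
# the t distribution with residual degrees of freedom.
# ---------------------------------------------------------------------------

default_covariates <- function() {
  c("age_band", "imd_band", "sex", "ethnicity", "chosen_symptom")
}

# Merge single-participant factor levels into the reference level so the
# design stays full rank (e.g. sex "other" with n=2 in the source cohort).
prepare_covariates <- function(data, covariates, quiet = FALSE) {
  drop <- character(0)
  for (v in covariates) {
    if (!v %in% names(data)) stop("missing covariate column '", v, "'")
    if (is.numeric(data[[v]])) {   # continuous covariates enter as they are
      if (stats::var(data[[v]]) == 0) drop <- c(drop, v)
      next
    }
    x <- as.character(data[[v]])
    tab <- table(x)
    if (length(tab) < 2L) {
      drop <- c(drop, v)
      next
    }
    ref <- names(tab)[which.max(tab)]
    rare <- names(tab)[tab < 2L]
    if (length(rare)) {
      if (!quiet) message("merging sparse level(s) of '", v, "' (",
                          paste(rare, collapse = ", "), ") into '", ref, "'")
      x[x %in% rare] <- ref
    }
    if (v == "ethnicity") {
      # analysis codes ethnicity as South Asian vs other
      x <- ifelse(x == "south_asian", "south_asian", "not_south_asian")
    }
    if (length(unique(x)) < 2L) { drop <- c(drop, v); next }
    data[[v]] <- stats::relevel(factor(x), ref = names(sort(table(x), decreasing = TRUE))[1L])
  }
  if (length(drop)) {
    if (!quiet) message("dropping single-level covariate(s): ", paste(drop, collapse = ", "))
    covariates <- setdiff(covariates, drop)
  }
  list(data = data, covariates = covariates)
}

effect_row <- function(outcome, visit, est, se, df, n, alpha = 0.05) {
  tcrit <- stats::qt(1 - alpha / 2, df)
  data.frame(outcome = outcome, visit_month = visit, estimate = est,
             se = se, ci_low = est - tcrit * se, ci_high = est + tcrit * se,
             p_value = 2 * stats::pt(-abs(est / se), df),
             n_analyzed = n, df = df)
}

#' Baseline-adjusted treatment effect (ANCOVA)
#'
#' Fits `outcome ~ arm + baseline + covariates` by least squares on
#' complete cases and returns the arm coefficient (intervention minus
#' control) with its t-based 95% CI and two-sided p-value.
#'
#' @param data data.frame with one row per participant containing the
#'   follow-up outcome, its baseline value, `arm`, and the covariates.
#' @param outcome,baseline column names of the follow-up and baseline
#'   outcome values.
#' @param covariates character vector of adjustment covariates (default
#'   the five stratification variables); sparse factor levels are merged
#'   into the reference level, single-level covariates dropped.
#' @param arm column holding the arm factor; the effect is the
#'   `"intervention"` level against `"control"`.
#' @param alpha two-sided significance level for the CI.
#' @param visit_month,label bookkeeping carried into the result row.
#' @param weights optional case weights (used by the IPW sensitivity
#'   analysis).
#' @return one-row data.frame: `outcome`, `visit_month`, `estimate`, `se`,
#'   `ci_low`, `ci_high`, `p_value`, `n_analyzed`, `df`; the fitted `lm`
#'   is attached as attribute `"fit"`.
#' @export
ancova_effect <- function(data, outcome, baseline,
                          covariates = default_covariates(),
                          arm = "arm", alpha = 0.05, visit_month = NA,
                          label = outcome, weights = NULL, quiet = TRUE) {
  stopifnot(all(c(outcome, baseline, arm) %in% names(data)))
  keep <- stats::complete.cases(data[c(outcome, baseline, arm, covariates)])
  if (!is.null(weights)) keep <- keep & !is.na(weights)
  data <- data[keep, , drop = FALSE]
  if (!is.null(weights)) weights <- weights[keep]
  if (nrow(data) == 0L) stop("no complete follow-up rows to analyze")
  prep <- prepare_covariates(data, covariates, quiet = quiet)
  data <- prep$data
  data[[arm]] <- factor(as.character(data[[arm]]), levels = c("control", "intervention"))
  if (any(is.na(data[[arm]]))) stop("arm must be 'control' or 'intervention'")
  if (length(unique(data[[arm]])) < 2L) stop("both arms required in the analysis set")
  base_term <- baseline
  if (stats::var(data[[baseline]]) == 0) {
    # a constant baseline carries no information; keep the model full rank
    if (!quiet) message("baseline '", baseline, "' is constant; dropped from the model")
    base_term <- NULL
  }
  rhs <- paste(c(arm, base_term, prep$covariates), collapse = " + ")
  fml <- stats::as.formula(paste(outcome, "~", rhs))
  data$.w <- if (is.null(weights)) rep(1, nrow(data)) else weights
  fit <- stats::lm(fml, data = data, weights = .w)
  cf <- summary(fit)$coefficients
  term <- paste0(arm, "intervention")
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("degenerate (collinear) design; offending term(s): ",
         paste(bad, collapse = ", "))
  }
  out <- effect_row(label, visit_month, cf[term, "Estimate"], cf[term, "Std. Error"],
                    fit$df.residual, nrow(data), alpha)
  attr(out, "fit") <- fit
  out
}

#' Treatment effect on repeated "other"-symptom ratings (mixed model)
#'
#' For participants reporting free-text "other" symptoms (several VAS
#' ratings per participant per visit), fits a linear mixed-effects model
#' within one visit: VAS rating on arm, baseline rating of the same
#' symptom, and the ANCOVA covariates, with a random intercept per
#' participant (REML; variance components at the zero boundary are
#' accepted). If every participant contributes a single row the model
#' collapses to ordinary least squares, which is then used with a notice.
#'
#' @param long data.frame with one row per participant-symptom at the
#'   analysis visit: `participant_id`, `arm`, `vas`, `vas_baseline`,
#'   covariates.
#' @param covariates adjustment covariates.
#' @param alpha CI level; `visit_month` bookkeeping.
#' @return one-row effect data.frame as [ancova_effect()] (df is the
#'   number of participants minus fixed effects for the mixed fit).
#' @export
mixed_other_effect <- function(long, covariates = default_covariates(),
                               alpha = 0.05, visit_month = NA, quiet = TRUE) {
  stopifnot(all(c("participant_id", "arm", "vas", "vas_baseline") %in% names(long)))
  keep <- stats::complete.cases(long[c("vas", "vas_baseline", "arm", covariates)])
  long <- long[keep, , drop = FALSE]
  prep <- prepare_covariates(long, covariates, quiet = quiet)
  long <- prep$data
  long$arm <- factor(as.character(long$arm), levels = c("control", "intervention"))
  n_id <- length(unique(long$participant_id))
  single_row <- n_id == nrow(long)
  rhs <- paste(c("arm", "vas_baseline", prep$covariates), collapse = " + ")
  if (single_row) {
    if (!quiet) message("one rating per participant: random intercept ",
                        "unidentifiable, falling back to least squares")
    out <- ancova_effect(long, "vas", "vas_baseline", prep$covariates,
                         alpha = alpha, visit_month = visit_month,
                         label = "other_symptoms", quiet = TRUE)
    attr(out, "model") <- "ols_fallback"
    return(out)
  }
  fml <- stats::as.formula(paste("vas ~", rhs, "+ (1 | participant_id)"))
  fit <- lme4::lmer(fml, data = long, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore",
                                                calc.derivs = FALSE))
  cf <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  term <- "armintervention"
  df <- n_id - length(cf)       # between-participant df for the arm contrast
  out <- effect_row("other_symptoms", visit_month, unname(cf[term]),
                    unname(se[which(names(cf) == term)]), df, nrow(long), alpha)
  out$n_participants <- n_id
  attr(out, "fit") <- fit
  attr(out, "model") <- "lmm"
  out
}

#' Subgroup treatment effects with interaction tests (forest-plot table)
#'
#' For each subgrouping variable, refits the ANCOVA within each level of
#' the variable and tests effect modification by adding a
#' group-by-variable interaction to the full-cohort model (F test against
#' the no-interaction model). Variables with a single observed level are
#' skipped with a warning. Subgroup analyses are descriptive: the design
#' is not powered for them.
#'
#' @param data analysis table as [ancova_effect()].
#' @param outcome,baseline,covariates,alpha as [ancova_effect()].
#' @param variables character vector of subgrouping columns. `bmi` (if
#'   named) is split into tertiles computed on the analyzed cohort;
#'   `age` into age tertiles; a `fatigue_chosen` indicator is derived
#'   from `chosen_symptom` if requested.
#' @return data.frame with one row per subgroup level (`variable`,
#'   `level`, effect columns, and the variable's `interaction_p`).
#' @export
subgroup_forest <- function(data, outcome, baseline,
                            variables = c("age", "imd_band", "bmi", "sex",
                                          "chosen_symptom", "fatigue_chosen"),
                            covariates = default_covariates(), alpha = 0.05,
                            visit_month = NA) {
  if ("fatigue_chosen" %in% variables && !"fatigue_chosen" %in% names(data) &&
      "chosen_symptom" %in% names(data)) {
    data$fatigue_chosen <- ifelse(data$chosen_symptom == "fatigue", "yes", "no")
  }
  tertile <- function(x) {
    q <- stats::quantile(x, c(1, 2) / 3, na.rm = TRUE, names = FALSE)
    cut(x, breaks = c(-Inf, q, Inf), labels = c("T1", "T2", "T3"))
  }
  rows <- list()
  for (v in variables) {
    if (!v %in% names(data)) { warning("subgroup variable '", v, "' absent; skipped"); next }
    g <- data[[v]]
    if (is.numeric(g) && length(unique(stats::na.omit(g))) > 3L) g <- tertile(g)
    g <- factor(as.character(g))
    if (nlevels(droplevels(g[!is.na(g)])) < 2L) {
      warning("subgroup variable '", v, "' has a single level; skipped")
      next
    }
    data$.grp <- g
    cov_v <- setdiff(covariates, v)
    keep <- stats::complete.cases(data[c(outcome, baseline, "arm", cov_v)]) & !is.na(g)
    d <- data[keep, , drop = FALSE]
    d$.grp <- droplevels(d$.grp)
    prep <- prepare_covariates(d, cov_v, quiet = TRUE)
    d <- prep$data
    d$arm <- factor(as.character(d$arm), levels = c("control", "intervention"))
    rhs0 <- paste(c("arm", baseline, prep$covariates, ".grp"), collapse = " + ")
    f0 <- stats::lm(stats::as.formula(paste(outcome, "~", rhs0)), data = d)
    f1 <- stats::lm(stats::as.formula(paste(outcome, "~", rhs0, "+ arm:.grp")), data = d)
    int_p <- stats::anova(f0, f1)[2, "Pr(>F)"]
    for (lev in levels(d$.grp)) {
      dl <- d[d$.grp == lev, , drop = FALSE]
      est <- tryCatch(
        ancova_effect(dl, outcome, baseline, prep$covariates, alpha = alpha,
                      visit_month = visit_month, label = outcome, quiet = TRUE),
        error = function(e) NULL)
      if (is.null(est)) next
      est$variable <- v
      est$level <- lev
      est$interaction_p <- int_p
      rows[[length(rows) + 1L]] <- est
    }
  }
  if (!length(rows)) return(data.frame())
  out <- do.call(rbind, lapply(rows, function(r) { attr(r, "fit") <- NULL; r }))
  rownames(out) <- NULL
  out
}

# ---------------------------------------------------------------------------
# Power and sample size for the standardized primary outcome, based on the
# two-sample t test with noncentral-t power.
# ---------------------------------------------------------------------------

#' Power of the two-sample t test (noncentral t)
#'
#' @param delta true between-group mean difference.
#' @param n1,n2 per-group sample sizes (>= 2).
#' @param sd common s.d. (1 for a standardized outcome).
#' @param alpha two-sided significance level.
#' @return power (probability of rejecting the null).
#' @export
power_t <- function(delta, n1, n2, sd = 1, alpha = 0.05) {
  stopifnot(n1 >= 2, n2 >= 2, sd > 0, alpha > 0, alpha < 1)
  df <- n1 + n2 - 2
  ncp <- abs(delta) / (sd * sqrt(1 / n1 + 1 / n2))
  tcrit <- stats::qt(1 - alpha / 2, df)
  stats::pt(tcrit, df, ncp, lower.tail = FALSE) + stats::pt(-tcrit, df, ncp)
}

#' Per-group sample size for the two-sample t test
#'
#' Smallest integer per-group n (equal groups) whose noncentral-t power
#' reaches the target.
#'
#' @param delta detectable difference (> 0); `sd`, `alpha` as [power_t()].
#' @param power target power.
#' @return integer per-group sample size.
#' @export
sample_size_t <- function(delta, power = 0.9, sd = 1, alpha = 0.05) {
  if (delta == 0) stop("delta = 0: requested power unattainable")
  stopifnot(power > 0, power < 1)
  # bracket with the normal approximation, then step to the exact integer
  n <- max(2, floor(2 * ((stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) * sd / abs(delta))^2))
  while (power_t(delta, n, n, sd, alpha) < power) n <- n + 1
  while (n > 2 && power_t(delta, n - 1, n - 1, sd, alpha) >= power) n <- n - 1
  as.integer(n)
}

#' Quality-adjusted life years by trapezoidal area under the utility curve
#'
#' @param utilities per-visit health-state utilities.
#' @param times_months visit times in months, strictly increasing.
#' @return QALYs (utility-weighted years).
#' @export
qaly_auc <- function(utilities, times_months) {
  if (length(utilities) < 2L || length(utilities) != length(times_months)) {
    stop("need >= 2 matched utility/time points")
  }
  if (any(diff(times_months) <= 0)) stop("times must be strictly increasing")
  if (anyNA(utilities)) return(NA_real_)
  years <- times_months / 12
  sum(diff(years) * (utilities[-1] + utilities[-length(utilities)]) / 2)
}

#' Change in weekly work hours missed, with adjusted group difference
#'
#' Computes each participant's change from baseline in hours of work
#' missed per week and the arm-level summaries, then the baseline-adjusted
#' group difference via [ancova_effect()]. Participants missing the
#' follow-up value are excluded from the effect and counted as attrition.
#'
#' @param data per-participant table with `arm`, covariates, `hours_baseline`
#'   and `hours_followup` (both >= 0).
#' @param covariates,alpha,visit_month as [ancova_effect()].
#' @return list: `summary` (per-arm mean change, sd, n), `effect`
#'   (adjusted difference), `n_missing` excluded.
#' @export
productivity_change <- function(data, covariates = default_covariates(),
                                alpha = 0.05, visit_month = NA) {
  stopifnot(all(c("hours_baseline", "hours_followup", "arm") %in% names(data)))
  neg <- c(data$hours_baseline, data$hours_followup)
  if (any(!is.na(neg) & neg < 0)) stop("work hours missed cannot be negative")
  data$hours_change <- data$hours_followup - data$hours_baseline
  n_missing <- sum(is.na(data$hours_change))
  smry <- do.call(rbind, lapply(split(data, data$arm), function(d) {
    ch <- d$hours_change[!is.na(d$hours_change)]
    data.frame(arm = d$arm[1], mean_change = mean(ch), sd_change = stats::sd(ch),
               n = length(ch))
  }))
  rownames(smry) <- NULL
  eff <- ancova_effect(data, "hours_followup", "hours_baseline", covariates,
                       alpha = alpha, visit_month = visit_month,
                       label = "work_hours_missed")
  list(summary = smry, effect = eff, n_missing = n_missing)
}
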
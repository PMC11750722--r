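# ---------------------------------------------------------------------------
# Missing-data sensitivity analyses: multiple imputation by chained
# equations (predictive mean matching for continuous variables, logistic /
# one-vs-rest multinomial for categorical), fitted separately within each
# arm, with Rubin's rules for pooling; and inverse-probability-of-
# follow-up weighting.
# ---------------------------------------------------------------------------

# Shared design-matrix builder: one model matrix over observed AND missing
# rows, so factor levels present only among the missing rows cannot break
# prediction; rank-deficient columns are dropped against the observed rows.
impute_design <- function(X_obs, X_mis) {
  X_all <- rbind(X_obs, X_mis)
  for (j in seq_along(X_all)) {
    if (is.character(X_all[[j]])) X_all[[j]] <- factor(X_all[[j]])
  }
  mm <- stats::model.matrix(~ ., data = X_all)
  obs <- seq_len(nrow(X_obs))
  q <- qr(mm[obs, , drop = FALSE])
  keep <- q$pivot[seq_len(q$rank)]
  list(obs = mm[obs, keep, drop = FALSE],
       mis = mm[-obs, keep, drop = FALSE])
}

# predictive mean matching, type-1: predict observed with beta_hat,
# missing with an approximate posterior draw, match each missing row to
# its `donors` nearest observed predictions, sample one donor's value.
pmm_impute_col <- function(y, X_obs, X_mis, donors = 5L) {
  dm <- impute_design(X_obs, X_mis)
  A <- dm$obs
  AtA <- crossprod(A)
  beta <- solve(AtA, crossprod(A, y))
  res <- y - A %*% beta
  df <- nrow(A) - ncol(A)
  beta_star <- beta
  if (df > 0 && sum(res^2) > 0) {
    sig2_star <- sum(res^2) / stats::rchisq(1, df)
    L <- tryCatch(chol(sig2_star * solve(AtA)), error = function(e) NULL)
    if (!is.null(L)) beta_star <- beta + drop(stats::rnorm(ncol(A)) %*% L)
  }
  pred_obs <- drop(A %*% beta)
  pred_mis <- drop(dm$mis %*% beta_star)
  vapply(pred_mis, function(p) {
    idx <- order(abs(pred_obs - p))[seq_len(min(donors, length(pred_obs)))]
    y[sample(idx, 1L)]
  }, numeric(1))
}

# logistic score on an explicit design matrix with a posterior coefficient
# draw; returns missing-row class-1 probabilities
logit_prob <- function(y01, dm) {
  fit <- suppressWarnings(stats::glm.fit(dm$obs, y01, family = stats::binomial()))
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  mu <- fit$fitted.values
  w <- pmax(mu * (1 - mu), 1e-8)
  V <- tryCatch(solve(crossprod(dm$obs * sqrt(w))), error = function(e) NULL)
  if (!is.null(V)) {
    L <- tryCatch(chol(V), error = function(e) NULL)
    if (!is.null(L)) beta <- beta + drop(stats::rnorm(length(beta)) %*% L)
  }
  stats::plogis(drop(dm$mis %*% beta))
}

cat_impute_col <- function(y, X_obs, X_mis) {
  lev <- levels(factor(y))
  if (length(lev) == 1L) return(rep(lev, nrow(X_mis)))
  dm <- impute_design(X_obs, X_mis)
  if (length(lev) == 2L) {
    p <- logit_prob(as.integer(y == lev[2L]), dm)
    return(lev[1L + stats::rbinom(length(p), 1L, p)])
  }
  # unordered k > 2: normalized one-vs-rest logistic
  probs <- vapply(lev, function(l) logit_prob(as.integer(y == l), dm),
                  numeric(nrow(X_mis)))
  probs <- matrix(probs, nrow = nrow(X_mis))
  apply(probs, 1L, function(p) sample(lev, 1L, prob = p / sum(p)))
}

impute_once <- function(data, imputable, predictors, cycles, donors) {
  miss <- lapply(data[imputable], is.na)
  active <- imputable[vapply(miss, any, logical(1))]
  if (!length(active)) return(data)
  # initialize holes with draws from the observed margin
  for (v in active) {
    obs <- data[[v]][!miss[[v]]]
    data[[v]][miss[[v]]] <- sample(obs, sum(miss[[v]]), replace = TRUE)
  }
  for (cyc in seq_len(cycles)) {
    for (v in active) {
      rhs <- union(setdiff(active, v), setdiff(predictors, v))
      rhs <- rhs[vapply(data[rhs], function(x) length(unique(x)) > 1L, logical(1))]
      X <- data[rhs]
      m <- miss[[v]]
      if (is.numeric(data[[v]])) {
        data[[v]][m] <- pmm_impute_col(data[[v]][!m], X[!m, , drop = FALSE],
                                       X[m, , drop = FALSE], donors)
      } else {
        imp <- cat_impute_col(as.character(data[[v]][!m]), X[!m, , drop = FALSE],
                              X[m, , drop = FALSE])
        data[[v]][m] <- imp
      }
    }
  }
  data
}

#' Multiple imputation by chained equations
#'
#' Produces `m` completed copies of `data`. Each incomplete imputable
#' column is modelled given the predictors and the other imputable
#' columns, cycling `cycles` times: predictive mean matching (5 donors by
#' default, with approximate-Bayesian parameter draws) for numeric
#' columns, logistic regression for two-level and normalized one-vs-rest
#' logistic for multi-level categorical columns. With `within_arm = TRUE`
#' (default, matching the trial's analysis plan) the chained equations are
#' fitted separately in each arm. Observed cells are never overwritten.
#'
#' @param data data.frame; missingness must be confined to `imputable`
#'   columns.
#' @param imputable columns whose missing values are to be imputed.
#' @param predictors complete columns used as predictors (e.g. the
#'   stratification variables plus BMI, education, physical activity,
#'   employment change and EQ-5D utility).
#' @param m number of imputations (the trial used 100).
#' @param within_arm impute separately per `arm`.
#' @param cycles chained-equation cycles per imputation.
#' @param donors PMM donor pool size.
#' @param seed RNG seed for reproducibility.
#' @return list of `m` completed data.frames.
#' @export
mice_impute <- function(data, imputable, predictors, m = 100,
                        within_arm = TRUE, cycles = 10, donors = 5,
                        seed = NULL) {
  stopifnot(m >= 2, length(predictors) >= 1)
  if (!is.null(seed)) set.seed(seed)
  stray <- setdiff(names(data)[vapply(data, anyNA, logical(1))], imputable)
  if (length(stray)) {
    stop("missing values outside declared imputable columns: ",
         paste(stray, collapse = ", "))
  }
  groups <- if (within_arm) {
    if (!"arm" %in% names(data)) stop("within_arm imputation requires an 'arm' column")
    split(seq_len(nrow(data)), data$arm)
  } else list(all = seq_len(nrow(data)))
  for (g in names(groups)) {
    for (v in imputable) {
      if (all(is.na(data[[v]][groups[[g]]]))) {
        stop("column '", v, "' fully missing within group '", g, "'")
      }
    }
  }
  lapply(seq_len(m), function(k) {
    out <- data
    for (idx in groups) {
      out[idx, ] <- impute_once(data[idx, , drop = FALSE], imputable,
                                predictors, cycles, donors)
    }
    out
  })
}

#' Pool per-imputation effect estimates by Rubin's rules
#'
#' Point estimate is the mean across imputations; total variance is the
#' mean within-imputation variance plus `(1 + 1/m)` times the
#' between-imputation variance. Degrees of freedom follow Rubin's
#' large-sample formula, or the Barnard-Rubin small-sample adjustment when
#' the complete-data degrees of freedom are supplied.
#'
#' @param estimates per-imputation point estimates.
#' @param ses matching standard errors.
#' @param df_complete complete-data residual df (Inf for the large-sample
#'   formula).
#' @param alpha two-sided CI level.
#' @return one-row data.frame: `estimate`, `se`, `ci_low`, `ci_high`,
#'   `p_value`, `m`, `between_var`, `within_var`, `total_var`, `df`.
#' @export
pool_rubin <- function(estimates, ses, df_complete = Inf, alpha = 0.05) {
  m <- length(estimates)
  if (m < 2 || length(ses) != m) stop("need m >= 2 matched estimates and standard errors")
  qbar <- mean(estimates)
  ubar <- mean(ses^2)
  b <- stats::var(estimates)
  t_var <- ubar + (1 + 1 / m) * b
  lambda <- (1 + 1 / m) * b / t_var
  df_old <- if (lambda > 0) (m - 1) / lambda^2 else Inf
  if (is.finite(df_complete)) {
    df_obs <- (df_complete + 1) / (df_complete + 3) * df_complete * (1 - lambda)
    df <- 1 / (1 / df_old + 1 / df_obs)
  } else df <- df_old
  se <- sqrt(t_var)
  q <- if (is.finite(df)) stats::qt(1 - alpha / 2, df) else stats::qnorm(1 - alpha / 2)
  p <- if (is.finite(df)) 2 * stats::pt(-abs(qbar / se), df) else
    2 * stats::pnorm(-abs(qbar / se))
  data.frame(estimate = qbar, se = se, ci_low = qbar - q * se,
             ci_high = qbar + q * se, p_value = p, m = m,
             between_var = b, within_var = ubar, total_var = t_var, df = df)
}

#' Pooled treatment effect over multiply imputed datasets
#'
#' Convenience wrapper: runs [ancova_effect()] on each completed dataset
#' and pools with [pool_rubin()].
#'
#' @param completed list of completed data.frames from [mice_impute()].
#' @param ... passed to [ancova_effect()].
#' @inheritParams pool_rubin
#' @return as [pool_rubin()].
#' @export
pooled_ancova <- function(completed, ..., alpha = 0.05) {
  fits <- lapply(completed, function(d) ancova_effect(d, ...))
  est <- vapply(fits, `[[`, numeric(1), "estimate")
  se <- vapply(fits, `[[`, numeric(1), "se")
  df_com <- fits[[1]]$df
  pool_rubin(est, se, df_complete = df_com, alpha = alpha)
}

#' Inverse-probability-of-follow-up weighted treatment effect
#'
#' Fits a logistic regression of the follow-up indicator on baseline
#' predictors, forms weights as the inverse fitted probability (truncated
#' below at `floor`, with truncations logged), and estimates the treatment
#' effect by weighted least squares with the ANCOVA covariate set on the
#' followed participants.
#'
#' @param data per-participant table; must contain the follow-up
#'   indicator, outcome and baseline columns, `arm` and the covariates.
#' @param followed name of the 0/1 follow-up indicator column.
#' @param predictors baseline predictors of follow-up (character vector of
#'   column names).
#' @param floor minimum allowed fitted follow-up probability.
#' @param outcome,baseline,covariates,alpha,visit_month as [ancova_effect()].
#' @return effect row as [ancova_effect()], with attributes `"weights"`
#'   (per followed participant) and `"n_truncated"`.
#' @export
ipw_effect <- function(data, followed, predictors, outcome, baseline,
                       covariates = default_covariates(), floor = 0.02,
                       alpha = 0.05, visit_month = NA, quiet = TRUE) {
  stopifnot(followed %in% names(data), all(predictors %in% names(data)))
  y <- data[[followed]]
  if (!all(y %in% c(0, 1))) stop("follow-up indicator must be 0/1")
  fml <- stats::as.formula(paste(followed, "~", paste(predictors, collapse = " + ")))
  pfit <- suppressWarnings(stats::glm(fml, data = data, family = stats::binomial()))
  p <- stats::predict(pfit, type = "response")
  n_trunc <- sum(p < floor)
  if (n_trunc > 0 && !quiet) {
    message(n_trunc, " follow-up probabilities below ", floor, "; truncated")
  }
  p <- pmax(p, floor)
  w <- 1 / p
  sub <- y == 1
  eff <- ancova_effect(data[sub, , drop = FALSE], outcome, baseline, covariates,
                       alpha = alpha, visit_month = visit_month,
                       label = outcome, weights = w[sub], quiet = quiet)
  attr(eff, "weights") <- w[sub]
  attr(eff, "n_truncated") <- n_trunc
  eff
}

#' Treatment effect given weight change, with and without interaction
#'
#' Post hoc analysis: ANCOVA of the outcome with the observed weight
#' change at a visit as an additional covariate, reported both without and
#' with a group-by-weight-change interaction term.
#'
#' @param data per-participant table with the outcome, baseline,
#'   `weight_change` column, `arm` and covariates.
#' @param outcome,baseline,covariates,alpha as [ancova_effect()].
#' @param weight_change name of the weight-change column (kg).
#' @return list: `no_interaction` (effect row), `interaction` (one-row
#'   data.frame for the interaction coefficient), `fit_interaction`.
#' @export
weight_interaction <- function(data, outcome, baseline,
                               weight_change = "weight_change",
                               covariates = default_covariates(),
                               alpha = 0.05, visit_month = NA) {
  stopifnot(weight_change %in% names(data))
  keep <- stats::complete.cases(data[c(outcome, baseline, "arm", weight_change, covariates)])
  d <- data[keep, , drop = FALSE]
  if (stats::var(d[[weight_change]]) == 0) {
    stop("weight change is constant: interaction inestimable")
  }
  prep <- prepare_covariates(d, covariates, quiet = TRUE)
  d <- prep$data
  d$arm <- factor(as.character(d$arm), levels = c("control", "intervention"))
  base_rhs <- paste(c("arm", baseline, weight_change, prep$covariates), collapse = " + ")
  f0 <- stats::lm(stats::as.formula(paste(outcome, "~", base_rhs)), data = d)
  f1 <- stats::lm(stats::as.formula(
    paste(outcome, "~", base_rhs, "+ arm:", weight_change)), data = d)
  cf0 <- summary(f0)$coefficients
  cf1 <- summary(f1)$coefficients
  int_term <- grep("^armintervention:", rownames(cf1), value = TRUE)
  if (!length(int_term) || anyNA(stats::coef(f1))) {
    stop("interaction inestimable (collinear design)")
  }
  no_int <- effect_row(outcome, visit_month, cf0["armintervention", "Estimate"],
                       cf0["armintervention", "Std. Error"], f0$df.residual,
                       nrow(d), alpha)
  int <- effect_row(paste0(outcome, ":", weight_change), visit_month,
                    cf1[int_term, "Estimate"], cf1[int_term, "Std. Error"],
                    f1$df.residual, nrow(d), alpha)
  list(no_interaction = no_int, interaction = int, fit_interaction = f1)
}
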
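# ---------------------------------------------------------------------------
# Synthetic trial generator. Emulates the reference cohort: the chosen-
# symptom mix, demographics and deprivation profile, baseline instrument
# distributions, the 0/3/6-month schedule, standardized treatment effects
# injected per visit, and differential (arm- and deprivation-dependent,
# monotone) attrition. Every generated trial carries its ground truth so
# analyses can be checked by parameter recovery.
# ---------------------------------------------------------------------------

other_symptom_pool <- function() {
  c("brain fog", "insomnia", "palpitations", "headache", "dizziness",
    "joint pain", "muscle ache", "loss of smell", "loss of taste",
    "tinnitus", "chest tightness", "nausea", "pins and needles",
    "poor concentration", "night sweats", "cough")
}

#' Parameterization of a synthetic trial
#'
#' Returns the default simulation specification as a named list; any field
#' can be overridden by name. Defaults encode the reference cohort:
#' 234 participants; chosen-symptom mix 54/16/12/1/17% (fatigue /
#' breathlessness / pain / anxiety-depression / other); 85% female; age
#' mean 46.3 (s.d. 9.8) banded at 50; 90% white; deprivation bands 53/47%;
#' standardized treatment effects -0.90 at month 3 and -0.34 at month 6;
#' baseline-follow-up correlation 0.5; attrition ~13%/16% (months 3/6) in
#' the intervention arm versus <1% in control, skewed toward the deprived
#' IMD band; about 3.5 free-text "other" symptoms per participant.
#' Baseline instrument means/s.d.s are plausible mid-scale values (the
#' per-subgroup values are not published) truncated to instrument ranges.
#'
#' @param ... named overrides of any default field.
#' @return object of class `simulation_spec`.
#' @export
simulation_spec <- function(...) {
  spec <- list(
    n = 234L,
    visits = c(3, 6),
    symptom_probs = c(fatigue = 0.54, breathlessness = 0.16, pain = 0.12,
                      anxiety_depression = 0.01, other = 0.17),
    min_subgroup = 3L,
    sex_probs = c(female = 0.85, male = 0.142, other = 0.008),
    age_mean = 46.3, age_sd = 9.8, age_cut = 50,
    ethnicity_probs = c(white = 0.90, south_asian = 0.04, other = 0.06),
    imd_probs = c("1-5" = 0.53, "6-10" = 0.47),
    bmi_mean = 36, bmi_sd = 5.5, bmi_min = 27.1,
    education_probs = c(secondary = 0.25, college = 0.30, degree = 0.45),
    activity_probs = c(low = 0.5, moderate = 0.35, high = 0.15),
    employment_change_probs = c(none = 0.6, reduced = 0.3, increased = 0.1),
    instruments = list(
      chalder = list(mean = 23, sd = 4.5, lo = 0, hi = 33, digits = 0),
      mrc_dyspnea = list(mean = 3.4, sd = 0.9, lo = 1, hi = 5, digits = 0),
      p4 = list(mean = 22, sd = 7, lo = 0, hi = 40, digits = 0),
      hads = list(mean = 21, sd = 7, lo = 0, hi = 42, digits = 0),
      vas = list(mean = 7, sd = 1.8, lo = 0, hi = 10, digits = 1)
    ),
    effects = c("3" = -0.90, "6" = -0.34),
    control_drift = c("3" = -0.30, "6" = -0.83),
    rho = 0.5,
    imd_outcome_shift = 0,     # z-shift at follow-up for the deprived band
    n_other_mean = 3.5,
    dropout = list(
      # cumulative loss of the primary outcome by visit and arm
      cumulative = list(control = c("3" = 0.002, "6" = 0.008),
                        intervention = c("3" = 0.13, "6" = 0.164)),
      imd_logodds = 1.0        # extra log-odds of dropout, deprived band
    ),
    secondary = list(
      weight_kg = list(baseline = c(101.9, 20.4), lo = 55, hi = 180,
                       change = list(intervention = list("3" = c(-9.8, 6.0), "6" = c(-10.3, 7.5)),
                                     control = list("3" = c(-1.3, 4.7), "6" = c(-0.7, 5.2)))),
      sbp_mmhg = list(baseline = c(131, 15), lo = 85, hi = 210,
                      change = list(intervention = list("3" = c(-4.0, 14.0), "6" = c(-6.6, 14.1)),
                                    control = list("3" = c(-1.5, 13.0), "6" = c(-3.2, 12.9)))),
      dbp_mmhg = list(baseline = c(82, 10), lo = 50, hi = 130,
                      change = list(intervention = list("3" = c(-3.0, 9.0), "6" = c(-4.7, 9.0)),
                                    control = list("3" = c(-1.0, 9.0), "6" = c(-1.8, 9.1)))),
      eq5d_utility = list(baseline = c(0.62, 0.22), lo = -0.4, hi = 1,
                          change = list(intervention = list("3" = c(0.06, 0.15), "6" = c(0.08, 0.15)),
                                        control = list("3" = c(0.01, 0.15), "6" = c(0.02, 0.15)))),
      eq5d_vas = list(baseline = c(55, 18), lo = 0, hi = 100,
                      change = list(intervention = list("3" = c(6, 15), "6" = c(8, 15)),
                                    control = list("3" = c(1, 15), "6" = c(2, 15)))),
      work_hours_missed = list(baseline = c(6, 11), lo = 0, hi = 80,
                               change = list(intervention = list("3" = c(-2.5, 13.5), "6" = c(-3.38, 13.97)),
                                             control = list("3" = c(-1.5, 13.5), "6" = c(-2.34, 14.03))))
    )
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(spec))
  if (length(bad)) stop("unknown simulation_spec field(s): ", paste(bad, collapse = ", "))
  spec[names(dots)] <- dots
  validate_spec(spec)
  structure(spec, class = "simulation_spec")
}

validate_spec <- function(spec) {
  for (p in list(spec$symptom_probs, spec$sex_probs, spec$ethnicity_probs,
                 spec$imd_probs, spec$education_probs, spec$activity_probs,
                 spec$employment_change_probs)) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8) stop("probabilities must be in [0,1] and sum to 1")
  }
  if (spec$n < 0) stop("n must be non-negative")
  if (!all(is.finite(spec$effects))) stop("effects must be finite")
  if (spec$rho < 0 || spec$rho >= 1) stop("rho must be in [0, 1)")
  cum <- spec$dropout$cumulative
  for (a in names(cum)) {
    if (any(cum[[a]] < 0 | cum[[a]] >= 1)) stop("cumulative dropout must be in [0, 1)")
    if (any(diff(cum[[a]]) < 0)) stop("cumulative dropout must be nondecreasing")
  }
  invisible(spec)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

draw_total <- function(n, ins) {
  round(clamp(stats::rnorm(n, ins$mean, ins$sd), ins$lo, ins$hi), ins$digits)
}

# Distribute integer totals across k items each bounded [0, item_max]:
# equal base allocation plus one extra point on `totals %% k` randomly
# chosen items, so items differ by at most 1 and sums are exact.
backfill_items <- function(totals, k, item_max) {
  stopifnot(all(totals >= 0), all(totals <= k * item_max))
  n <- length(totals)
  q <- totals %/% k
  r <- totals %% k
  m <- matrix(rep(q, k), nrow = n)
  if (any(r > 0)) {
    u <- matrix(stats::runif(n * k), n)
    # row-wise ranks without apply(): rank = 1 + number of smaller entries
    rk <- matrix(1L, n, k)
    for (j in seq_len(k)) rk[, j] <- rk[, j] + rowSums(u < u[, j])
    m <- m + (rk <= r)       # recycles r column-wise over the n x k matrix
  }
  m
}

split_hads <- function(totals) {
  # split a 0-42 total into anxiety/depression halves, each 0-21
  anx <- stats::rbinom(length(totals), totals, 0.5)
  anx <- clamp(anx, pmax(0, totals - 21), pmin(21, totals))
  cbind(anxiety = anx, depression = totals - anx)
}

instrument_items_df <- function(n, chalder_tot, hads_tot, p4_tot) {
  ch <- backfill_items(chalder_tot, 11L, 3L)
  colnames(ch) <- sprintf("chalder_%02d", 1:11)
  hs <- split_hads(hads_tot)
  ha <- backfill_items(hs[, "anxiety"], 7L, 3L)
  colnames(ha) <- sprintf("hads_a%d", 1:7)
  hd <- backfill_items(hs[, "depression"], 7L, 3L)
  colnames(hd) <- sprintf("hads_d%d", 1:7)
  p4 <- backfill_items(p4_tot, 4L, 10L)
  colnames(p4) <- sprintf("p4_%d", 1:4)
  as.data.frame(cbind(ch, ha, hd, p4))
}

draw_symptoms <- function(n, probs, min_subgroup) {
  sym <- sample(names(probs), n, replace = TRUE, prob = probs)
  # guarantee a standardizable stratum wherever the spec puts mass: top up
  # any positive-probability symptom below min_subgroup from the largest
  # stratum (the trial's smallest stratum had 3 choosers)
  if (min_subgroup > 0) {
    for (s in names(probs)[probs > 0]) {
      deficit <- min_subgroup - sum(sym == s)
      if (deficit > 0) {
        big <- names(which.max(table(sym)))
        take <- sample(which(sym == big), deficit)
        sym[take] <- s
      }
    }
  }
  sym
}

#' Generate a synthetic baseline cohort
#'
#' Draws `spec$n` participants: stratification profiles from the spec
#' frequencies, baseline covariates, item-level instrument responses whose
#' totals follow the spec's truncated distributions (items back-filled by
#' constrained allocation), and free-text "other" symptoms (each "other"
#' chooser's first label is their baseline main symptom).
#'
#' @param spec a [simulation_spec()].
#' @return list: `cohort` (one row per participant), `visits` (baseline
#'   visit records), `other` (baseline other-symptom VAS table).
#' @export
generate_cohort <- function(spec) {
  n <- spec$n
  if (n <= 0) stop("spec$n must be positive to generate a cohort")
  id <- sprintf("P%04d", seq_len(n))
  age <- round(clamp(stats::rnorm(n, spec$age_mean, spec$age_sd), 18, 85))
  cohort <- data.frame(
    participant_id = id,
    chosen_symptom = draw_symptoms(n, spec$symptom_probs, spec$min_subgroup),
    sex = sample(names(spec$sex_probs), n, TRUE, spec$sex_probs),
    age = age,
    age_band = ifelse(age < spec$age_cut, "<50", "50+"),
    ethnicity = sample(names(spec$ethnicity_probs), n, TRUE, spec$ethnicity_probs),
    imd_band = sample(names(spec$imd_probs), n, TRUE, spec$imd_probs),
    bmi = round(pmax(stats::rnorm(n, spec$bmi_mean, spec$bmi_sd), spec$bmi_min), 1),
    education = sample(names(spec$education_probs), n, TRUE, spec$education_probs),
    physical_activity = sample(names(spec$activity_probs), n, TRUE, spec$activity_probs),
    employment_change = sample(names(spec$employment_change_probs), n, TRUE,
                               spec$employment_change_probs),
    main_other_symptom = NA_character_,
    stringsAsFactors = FALSE
  )

  # free-text symptoms: roughly n_other_mean per participant cohort-wide;
  # "other" choosers always have at least one (their main symptom)
  pool <- other_symptom_pool()
  n_other <- stats::rpois(n, spec$n_other_mean)
  is_other <- cohort$chosen_symptom == "other"
  n_other[is_other] <- pmax(1L, n_other[is_other])
  n_other <- pmin(n_other, length(pool))
  labels <- lapply(n_other, function(k) if (k > 0) sample(pool, k) else character(0))
  cohort$main_other_symptom[is_other] <-
    vapply(labels[is_other], `[`, character(1), 1L)

  ins <- spec$instruments
  baseline <- data.frame(
    participant_id = id, visit_month = 0,
    mrc_dyspnea = draw_total(n, ins$mrc_dyspnea),
    eq5d_vas = draw_total_sec(n, spec$secondary$eq5d_vas, 0),
    eq5d_utility = draw_total_sec(n, spec$secondary$eq5d_utility, 3),
    weight_kg = draw_total_sec(n, spec$secondary$weight_kg, 1),
    sbp_mmhg = draw_total_sec(n, spec$secondary$sbp_mmhg, 0),
    dbp_mmhg = draw_total_sec(n, spec$secondary$dbp_mmhg, 0),
    work_hours_missed = draw_total_sec(n, spec$secondary$work_hours_missed, 1)
  )
  baseline <- cbind(baseline, instrument_items_df(
    n, draw_total(n, ins$chalder), draw_total(n, ins$hads), draw_total(n, ins$p4)))

  other <- data.frame(
    participant_id = rep(id, n_other),
    visit_month = 0,
    symptom_label = unlist(labels),
    vas = draw_total(sum(n_other), ins$vas),
    stringsAsFactors = FALSE
  )
  list(cohort = cohort, visits = validate_visits(baseline, other)$visits,
       other = other)
}

draw_total_sec <- function(n, s, digits) {
  round(clamp(stats::rnorm(n, s$baseline[1], s$baseline[2]), s$lo, s$hi), digits)
}

followup_total <- function(raw0, ins, drift, effect_z, rho, noise) {
  z0 <- (raw0 - ins$mean) / ins$sd
  z1 <- drift + effect_z + rho * z0 + sqrt(1 - rho^2) * noise
  round(clamp(ins$mean + ins$sd * z1, ins$lo, ins$hi), ins$digits)
}

#' Generate follow-up visit records for an allocated cohort
#'
#' Follow-up symptom scores are baseline-correlated draws (correlation
#' `spec$rho`) shifted by a secular drift shared by both arms plus, in the
#' intervention arm, the spec's standardized per-visit effect, converted
#' back to instrument units through the instrument s.d. and truncated to
#' the instrument range. Secondary outcomes (weight, blood pressure,
#' EQ-5D, work hours) get arm-specific change draws of the configured
#' magnitudes. Effects are injected on the standardized scale, so the
#' target ANCOVA estimand of the standardized primary outcome equals the
#' spec effect by construction.
#'
#' @param cohort cohort table carrying an `arm` column.
#' @param baseline baseline visit records from [generate_cohort()].
#' @param other_baseline baseline other-symptom table.
#' @param spec the [simulation_spec()].
#' @return list: `visits` (rows for each month in `spec$visits`), `other`
#'   (follow-up VAS rows for every tracked label).
#' @export
generate_followup <- function(cohort, baseline, other_baseline, spec) {
  if (!"arm" %in% names(cohort) || anyNA(cohort$arm)) {
    stop("cohort must be fully allocated to arms before follow-up generation")
  }
  n <- nrow(cohort)
  ord <- match(cohort$participant_id, baseline$participant_id)
  stopifnot(!anyNA(ord))
  b <- baseline[ord, , drop = FALSE]
  interv <- cohort$arm == "intervention"
  deprived <- cohort$imd_band == names(spec$imd_probs)[1]
  ins <- spec$instruments
  visits_out <- list(); other_out <- list()
  for (v in spec$visits) {
    vch <- as.character(v)
    drift <- spec$control_drift[[vch]]
    eff <- spec$effects[[vch]] * interv + spec$imd_outcome_shift * deprived
    ch <- followup_total(b$chalder_total, ins$chalder, drift, eff, spec$rho, stats::rnorm(n))
    hd <- followup_total(b$hads_total, ins$hads, drift, eff, spec$rho, stats::rnorm(n))
    p4 <- followup_total(b$p4_total, ins$p4, drift, eff, spec$rho, stats::rnorm(n))
    mrc <- followup_total(b$mrc_dyspnea, ins$mrc_dyspnea, drift, eff, spec$rho, stats::rnorm(n))
    vis <- data.frame(participant_id = cohort$participant_id, visit_month = v,
                      mrc_dyspnea = mrc)
    for (s in names(spec$secondary)) {
      par <- spec$secondary[[s]]
      chg <- matrix(NA_real_, n, 2)
      for (a in c("control", "intervention")) {
        i <- if (a == "intervention") interv else !interv
        cc <- par$change[[a]][[vch]]
        chg[i, 1] <- cc[1]; chg[i, 2] <- cc[2]
      }
      digits <- if (s == "eq5d_utility") 3 else if (s %in% c("weight_kg", "work_hours_missed")) 1 else 0
      vis[[s]] <- round(clamp(b[[s]] + stats::rnorm(n, chg[, 1], chg[, 2]),
                              par$lo, par$hi), digits)
    }
    vis <- cbind(vis, instrument_items_df(n, ch, hd, p4))
    visits_out[[vch]] <- vis

    if (nrow(other_baseline)) {
      oi <- match(other_baseline$participant_id, cohort$participant_id)
      od <- drift + spec$effects[[vch]] * interv[oi] + spec$imd_outcome_shift * deprived[oi]
      z0 <- (other_baseline$vas - ins$vas$mean) / ins$vas$sd
      z1 <- od + spec$rho * z0 + sqrt(1 - spec$rho^2) * stats::rnorm(nrow(other_baseline))
      other_out[[vch]] <- data.frame(
        participant_id = other_baseline$participant_id, visit_month = v,
        symptom_label = other_baseline$symptom_label,
        vas = round(clamp(ins$vas$mean + ins$vas$sd * z1, ins$vas$lo, ins$vas$hi),
                    ins$vas$digits),
        stringsAsFactors = FALSE)
    }
  }
  list(visits = do.call(rbind, visits_out), other = do.call(rbind, other_out))
}

# per-visit incremental dropout hazards from the cumulative targets
incremental_hazards <- function(cumulative) {
  h <- cumulative
  surv <- 1
  for (i in seq_along(cumulative)) {
    prev <- if (i == 1) 0 else cumulative[i - 1]
    h[i] <- (cumulative[i] - prev) / (1 - prev)
    surv <- surv * (1 - h[i])
  }
  h
}

# intercept a with mean(plogis(a + b * deprived)) = target over the IMD mix
calibrate_intercept <- function(target, b, p_deprived) {
  if (target <= 0) return(-Inf)
  f <- function(a) p_deprived * stats::plogis(a + b) +
    (1 - p_deprived) * stats::plogis(a) - target
  stats::uniroot(f, c(-30, 30))$root
}

#' Apply arm- and deprivation-dependent attrition to follow-up visits
#'
#' Draws per-participant per-visit dropout from a logistic model with a
#' per-visit, per-arm intercept (calibrated so marginal loss matches the
#' spec's cumulative targets over the IMD mix) plus a log-odds shift for
#' the deprived IMD band. Missingness is monotone: once lost, a
#' participant stays lost. Lost participant-visits are removed from the
#' visit and other-symptom tables, and a follow-up indicator table is
#' returned for inverse-probability weighting.
#'
#' @param visits follow-up visit records.
#' @param other follow-up other-symptom table (may be NULL).
#' @param cohort allocated cohort.
#' @param spec the [simulation_spec()].
#' @return list: `visits`, `other` (rows of lost participant-visits
#'   removed) and `followup` (participant by visit 0/1 indicator table).
#' @export
apply_attrition <- function(visits, other, cohort, spec) {
  n <- nrow(cohort)
  deprived <- cohort$imd_band == names(spec$imd_probs)[1]
  b <- spec$dropout$imd_logodds
  p_dep <- spec$imd_probs[[1]]
  lost <- rep(FALSE, n)
  fu <- data.frame(participant_id = cohort$participant_id)
  for (v in spec$visits) {
    vch <- as.character(v)
    for (a in c("control", "intervention")) {
      haz <- incremental_hazards(spec$dropout$cumulative[[a]])[[vch]]
      int <- calibrate_intercept(haz, b, p_dep)
      i <- which(cohort$arm == a & !lost)
      if (length(i) && is.finite(int)) {
        p <- stats::plogis(int + b * deprived[i])
        lost[i] <- stats::runif(length(i)) < p
      }
    }
    fu[[paste0("followed_", v)]] <- as.integer(!lost)
    drop_ids <- cohort$participant_id[lost]
    visits <- visits[!(visits$visit_month == v & visits$participant_id %in% drop_ids), ]
    if (!is.null(other)) {
      other <- other[!(other$visit_month == v & other$participant_id %in% drop_ids), ]
    }
  }
  list(visits = visits, other = other, followup = fu)
}

#' Generate a complete synthetic trial
#'
#' Cohort generation, allocation (minimization with an 80:20 random
#' element by default, or exact alternation, or none), follow-up outcome
#' generation and attrition, bundled with the ground truth.
#'
#' @param spec a [simulation_spec()].
#' @param seed optional RNG seed.
#' @param allocation `"minimization"`, `"exact"` (deterministic 1:1
#'   alternation; useful for calibration studies needing fixed arm sizes)
#'   or `"none"` (baseline only).
#' @param p_deterministic minimization mixing weight.
#' @param attrition apply the dropout model.
#' @return list of class `synthetic_trial`: `cohort`, `visits` (baseline +
#'   follow-up), `other`, `followup` indicator table, `allocation_log`,
#'   `ground_truth` (true per-visit standardized effects, dropout model,
#'   seed), `spec`.
#' @export
generate_trial <- function(spec = simulation_spec(), seed = NULL,
                           allocation = c("minimization", "exact", "none"),
                           p_deterministic = 0.8, attrition = TRUE) {
  allocation <- match.arg(allocation)
  if (!is.null(seed)) set.seed(seed)
  base <- generate_cohort(spec)
  cohort <- base$cohort
  alloc_log <- NULL
  if (allocation == "minimization") {
    alloc_log <- minimize_allocate(cohort, p_deterministic = p_deterministic)
    cohort$arm <- alloc_log$arm
  } else if (allocation == "exact") {
    cohort$arm <- rep_len(c("control", "intervention"), nrow(cohort))
  }
  visits <- base$visits
  other <- base$other
  fu <- NULL
  if (allocation != "none") {
    fol <- generate_followup(cohort, base$visits, base$other, spec)
    if (attrition) {
      att <- apply_attrition(fol$visits, fol$other, cohort, spec)
      fol$visits <- att$visits; fol$other <- att$other; fu <- att$followup
    }
    fol$visits <- validate_visits(fol$visits)$visits
    visits <- rbind(base$visits, fol$visits[names(base$visits)])
    other <- rbind(base$other, fol$other)
  }
  structure(list(
    cohort = cohort, visits = visits, other = other, followup = fu,
    allocation_log = alloc_log,
    ground_truth = list(effects = spec$effects, rho = spec$rho,
                        dropout = spec$dropout, seed = seed),
    spec = spec), class = "synthetic_trial")
}

#' Primary-outcome analysis of a (synthetic or real) trial
#'
#' Runs the pipeline: fit baseline references on all randomized
#' participants, build the standardized respective outcome, and estimate
#' the baseline-adjusted treatment effect at each requested visit.
#'
#' @param trial list with `cohort`, `visits`, `other` (a `synthetic_trial`
#'   or equivalently shaped data).
#' @param visits follow-up months to analyze.
#' @param covariates,alpha passed to [ancova_effect()].
#' @return list: `effects` (one row per visit), `outcome` (the z table),
#'   `references`.
#' @export
analyze_trial <- function(trial, visits = c(3, 6),
                          covariates = default_covariates(), alpha = 0.05) {
  z <- build_primary_outcome(trial$cohort, trial$visits, trial$other)
  refs <- attr(z, "references")
  wide <- merge(trial$cohort, z[z$visit_month == 0, c("participant_id", "z")],
                by = "participant_id")
  names(wide)[names(wide) == "z"] <- "z0"
  effects <- list()
  for (v in visits) {
    zv <- z[z$visit_month == v, c("participant_id", "z")]
    if (!nrow(zv)) stop("no follow-up outcome rows at month ", v)
    d <- merge(wide, zv, by = "participant_id")
    effects[[as.character(v)]] <- ancova_effect(
      d, "z", "z0", covariates, alpha = alpha, visit_month = v,
      label = "respective_primary")
  }
  effects <- do.call(rbind, effects)
  rownames(effects) <- NULL
  list(effects = effects, outcome = z, references = refs)
}

#' Replicate trial generation and analysis for calibration studies
#'
#' Generates `replicates` independent trials from `spec` and records the
#' estimated primary-outcome effect at one visit per replicate. Rare
#' replicates whose random cohort yields a degenerate standardization
#' subgroup raise an error by design; these are caught, counted and
#' excluded rather than aborting the study.
#'
#' @param spec a [simulation_spec()].
#' @param replicates number of simulated trials.
#' @param visit follow-up month analyzed.
#' @param seed RNG seed for the whole study.
#' @param allocation,attrition passed to [generate_trial()].
#' @return data.frame (one row per successful replicate): `estimate`,
#'   `ci_low`, `ci_high`, `p_value`, `n_analyzed`; attribute `"n_failed"`.
#' @export
recover_effects <- function(spec, replicates, visit = 6, seed = NULL,
                            allocation = "minimization", attrition = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  rows <- vector("list", replicates)
  failed <- 0L
  for (r in seq_len(replicates)) {
    rows[[r]] <- tryCatch({
      trial <- generate_trial(spec, allocation = allocation, attrition = attrition)
      analyze_trial(trial, visits = visit)$effects
    }, error = function(e) { NULL })
    if (is.null(rows[[r]])) failed <- failed + 1L
  }
  out <- do.call(rbind, rows)
  attr(out, "n_failed") <- failed
  out
}
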
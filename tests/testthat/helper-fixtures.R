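# Fixtures are built in code so the suite needs no data files.

update_state_for_test <- function(st, p, arm) respectr:::update_state(st, p, arm)
default_covariates_for_test <- function()
  c("age_band", "imd_band", "sex", "ethnicity", "chosen_symptom")
sample_profiles_for_test <- function(n, freqs) respectr:::sample_profiles(n, freqs)

# A hand-written ten-participant trial, two choosers per symptom stratum
# (the minimum for a finite reference), used for oracle-equivalence tests.
# Instrument totals are chosen so reference means/s.d.s are easy to verify
# by hand: fatigue baselines {20, 28} -> mean 24, sd sqrt(32), etc.
tiny_trial <- function() {
  cohort <- data.frame(
    participant_id = sprintf("T%02d", 1:10),
    chosen_symptom = rep(c("fatigue", "breathlessness", "pain",
                           "anxiety_depression", "other"), each = 2),
    main_other_symptom = c(rep(NA, 8), "brain fog", "insomnia"),
    sex = rep(c("female", "male"), 5),
    age_band = rep(c("<50", "50+"), 5),
    ethnicity = c(rep("white", 8), "south_asian", "other"),
    imd_band = rep(c("1-5", "6-10"), 5),
    arm = rep(c("control", "intervention"), 5),
    stringsAsFactors = FALSE
  )
  visits <- data.frame(
    participant_id = rep(cohort$participant_id, times = 2),
    visit_month = rep(c(0, 6), each = 10),
    chalder_total = c(20, 28, rep(15, 8), 18, 24, rep(15, 8)),
    mrc_dyspnea = c(2, 2, 4, 2, rep(2, 6), 2, 2, 3, 2, rep(2, 6)),
    p4_total = c(rep(10, 4), 24, 10, rep(10, 4), rep(10, 4), 20, 10, rep(10, 4)),
    hads_total = c(rep(10, 6), 13, 9, 10, 10, rep(10, 6), 11, 9, 10, 10)
  )
  other <- data.frame(
    participant_id = c("T09", "T09", "T10", "T09", "T10"),
    visit_month = c(0, 0, 0, 6, 6),
    symptom_label = c("brain fog", "palpitations", "insomnia", "brain fog",
                      "insomnia"),
    vas = c(7, 4, 3, 5, 4),
    stringsAsFactors = FALSE
  )
  list(cohort = cohort, visits = visits, other = other)
}

# independent per-participant standardization oracle: plain loops, no
# shared code with the package implementation
oracle_primary <- function(cohort, visits, other) {
  raw_of <- function(pid, month) {
    sym <- cohort$chosen_symptom[cohort$participant_id == pid]
    row <- visits[visits$participant_id == pid & visits$visit_month == month, ]
    if (sym == "fatigue") return(row$chalder_total)
    if (sym == "breathlessness") return(row$mrc_dyspnea)
    if (sym == "pain") return(row$p4_total)
    if (sym == "anxiety_depression") return(row$hads_total)
    lab <- tolower(trimws(cohort$main_other_symptom[cohort$participant_id == pid]))
    v <- other$vas[other$participant_id == pid & other$visit_month == month &
                     tolower(trimws(other$symptom_label)) == lab]
    if (length(v)) v else NA_real_
  }
  out <- NULL
  for (pid in cohort$participant_id) {
    sym <- cohort$chosen_symptom[cohort$participant_id == pid]
    peers <- cohort$participant_id[cohort$chosen_symptom == sym]
    base <- vapply(peers, raw_of, numeric(1), month = 0)
    m <- mean(base); s <- sd(base)
    for (month in unique(visits$visit_month)) {
      r <- raw_of(pid, month)
      if (!is.na(r)) {
        out <- rbind(out, data.frame(participant_id = pid, visit_month = month,
                                     z = (r - m) / s))
      }
    }
  }
  out
}

# wide per-participant analysis table (baseline z + follow-up z) from a trial
primary_wide <- function(trial, visit) {
  z <- build_primary_outcome(trial$cohort, trial$visits, trial$other)
  w <- merge(trial$cohort,
             setNames(z[z$visit_month == 0, c("participant_id", "z")],
                      c("participant_id", "z0")), by = "participant_id")
  merge(w, z[z$visit_month == visit, c("participant_id", "z")],
        by = "participant_id")
}

# small synthetic analysis table generated directly on the z scale (fast
# path for regression-machinery tests that do not need the full pipeline)
sim_z_data <- function(n = 120, effect = 0, rho = 0.5, seed = NULL,
                       imd_shift = 0) {
  if (!is.null(seed)) set.seed(seed)
  arm <- rep(c("control", "intervention"), length.out = n)
  imd <- sample(c("1-5", "6-10"), n, TRUE)
  z0 <- rnorm(n)
  z <- effect * (arm == "intervention") + imd_shift * (imd == "1-5") +
    rho * z0 + sqrt(1 - rho^2) * rnorm(n)
  data.frame(participant_id = seq_len(n), arm = arm, imd_band = imd,
             sex = sample(c("female", "male"), n, TRUE),
             age_band = sample(c("<50", "50+"), n, TRUE),
             ethnicity = sample(c("white", "south_asian", "other"), n, TRUE,
                                prob = c(.9, .04, .06)),
             chosen_symptom = sample(c("fatigue", "breathlessness", "pain"),
                                     n, TRUE, prob = c(.6, .2, .2)),
             z0 = z0, z = z, stringsAsFactors = FALSE)
}
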
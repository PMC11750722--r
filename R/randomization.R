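# ---------------------------------------------------------------------------
# Covariate-adaptive allocation: Pocock-Simon minimization over the trial's
# five stratification factors (chosen symptom, sex, age band, ethnicity,
# IMD band) with an 80:20 deterministic:random element and 1:1 target.
# ---------------------------------------------------------------------------

#' Default stratification factor levels
#'
#' The five minimization factors: participant-chosen dominant symptom,
#' sex, age band (<50 / 50+), ethnicity (white / South Asian / other) and
#' postcode deprivation band (IMD deciles 1-5 / 6-10).
#' @return named list of character level vectors.
#' @export
stratification_factors <- function() {
  list(
    chosen_symptom = all_symptoms(),
    sex = c("female", "male", "other"),
    age_band = c("<50", "50+"),
    ethnicity = c("white", "south_asian", "other"),
    imd_band = c("1-5", "6-10")
  )
}

#' Create an empty allocation state
#'
#' Holds, for each factor, the per-arm count of previously allocated
#' participants at each level, plus per-arm totals.
#'
#' @param factors named list of level vectors (default
#'   [stratification_factors()]).
#' @param arms arm labels (two).
#' @return object of class `allocation_state`.
#' @export
allocation_state <- function(factors = stratification_factors(),
                             arms = c("control", "intervention")) {
  stopifnot(length(arms) == 2L, is.list(factors), length(factors) >= 1L)
  counts <- lapply(factors, function(lv) {
    m <- matrix(0L, nrow = length(lv), ncol = 2L, dimnames = list(lv, arms))
    m
  })
  structure(list(counts = counts, totals = setNames(c(0L, 0L), arms),
                 factors = factors, arms = arms),
            class = "allocation_state")
}

check_profile <- function(state, profile) {
  for (f in names(state$factors)) {
    if (!f %in% names(profile)) stop("profile lacks factor '", f, "'")
    if (!profile[[f]] %in% state$factors[[f]]) {
      stop("unknown level '", profile[[f]], "' for factor '", f, "'")
    }
  }
  invisible(TRUE)
}

#' Marginal imbalance if a participant were assigned to an arm
#'
#' Pocock-Simon marginal metric with equal factor weights: the sum over
#' factors of the absolute between-arm difference in counts at the
#' participant's own level, computed as if the participant were assigned
#' to `arm`. Optionally the arm totals are added as a further component.
#'
#' @param state an `allocation_state`.
#' @param profile named list/vector giving the participant's level on each
#'   factor.
#' @param arm candidate arm.
#' @param include_arm_size also count overall arm-size imbalance.
#' @return numeric imbalance score.
#' @export
imbalance_if <- function(state, profile, arm, include_arm_size = FALSE) {
  check_profile(state, profile)
  arm <- match.arg(arm, state$arms)
  other <- setdiff(state$arms, arm)
  s <- 0
  for (f in names(state$factors)) {
    lv <- as.character(profile[[f]])
    s <- s + abs((state$counts[[f]][lv, arm] + 1L) - state$counts[[f]][lv, other])
  }
  if (include_arm_size) {
    s <- s + abs((state$totals[arm] + 1L) - state$totals[other])
  }
  unname(s)
}

update_state <- function(state, profile, arm) {
  for (f in names(state$factors)) {
    lv <- as.character(profile[[f]])
    state$counts[[f]][lv, arm] <- state$counts[[f]][lv, arm] + 1L
  }
  state$totals[arm] <- state$totals[arm] + 1L
  state
}

#' Assign one participant by minimization with a random element
#'
#' The arm that strictly minimizes [imbalance_if()] is chosen with
#' probability `p_deterministic` (default 0.8, i.e. an 80:20 mix of
#' minimization and randomization); ties are broken by a fair coin.
#'
#' @param state an `allocation_state`.
#' @param profile participant's stratification profile.
#' @param p_deterministic probability of following the minimizing arm,
#'   in \[0.5, 1\].
#' @param include_arm_size passed to [imbalance_if()].
#' @return list with `arm`, updated `state`, and a one-row `log`
#'   data.frame (imbalance per arm, random draw, assigned arm).
#' @export
assign_arm <- function(state, profile, p_deterministic = 0.8,
                       include_arm_size = FALSE) {
  stopifnot(p_deterministic >= 0.5, p_deterministic <= 1)
  d <- vapply(state$arms, function(a)
    imbalance_if(state, profile, a, include_arm_size), numeric(1))
  u <- stats::runif(1)
  if (d[1L] == d[2L]) {
    arm <- state$arms[if (u < 0.5) 1L else 2L]
  } else {
    best <- state$arms[which.min(d)]
    worst <- setdiff(state$arms, best)
    arm <- if (u < p_deterministic) best else worst
  }
  state <- update_state(state, profile, arm)
  list(arm = arm, state = state,
       log = data.frame(imbalance_control = unname(d[1L]),
                        imbalance_intervention = unname(d[2L]),
                        draw = u, arm = arm))
}

#' Allocate a sequence of participants by minimization
#'
#' @param profiles data.frame, one row per participant in arrival order,
#'   with one column per stratification factor (and optionally
#'   `participant_id`).
#' @param p_deterministic,include_arm_size see [assign_arm()].
#' @param factors named list of levels; defaults to
#'   [stratification_factors()] restricted to columns present.
#' @param seed optional integer seed for reproducible allocation.
#' @return data.frame allocation log: `sequence`, `participant_id`, the
#'   profile columns, per-arm imbalance, `draw`, `arm`; attribute
#'   `"state"` carries the final `allocation_state`.
#' @export
minimize_allocate <- function(profiles, p_deterministic = 0.8,
                              include_arm_size = FALSE, factors = NULL,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(factors)) {
    factors <- stratification_factors()
    factors <- factors[intersect(names(factors), names(profiles))]
  }
  if (!length(factors)) stop("no stratification factor columns found in profiles")
  stopifnot(p_deterministic >= 0.5, p_deterministic <= 1)
  state <- allocation_state(factors)
  n <- nrow(profiles)
  nf <- length(factors)
  # integer level codes per factor, validated up front (fast inner loop)
  codes <- matrix(0L, n, nf)
  for (j in seq_len(nf)) {
    f <- names(factors)[j]
    codes[, j] <- match(as.character(profiles[[f]]), factors[[f]])
    if (anyNA(codes[, j])) {
      stop("unknown level '",
           profiles[[f]][which(is.na(codes[, j]))[1]], "' for factor '", f, "'")
    }
  }
  dA <- dB <- numeric(n); draws <- numeric(n); arm_i <- integer(n)
  for (i in seq_len(n)) {
    a <- b <- 0
    for (j in seq_len(nf)) {
      cnt <- state$counts[[j]][codes[i, j], ]
      a <- a + abs(cnt[1L] + 1L - cnt[2L])
      b <- b + abs(cnt[2L] + 1L - cnt[1L])
    }
    if (include_arm_size) {
      a <- a + abs(state$totals[1L] + 1L - state$totals[2L])
      b <- b + abs(state$totals[2L] + 1L - state$totals[1L])
    }
    u <- stats::runif(1)
    k <- if (a == b) { if (u < 0.5) 1L else 2L }
         else if (a < b) { if (u < p_deterministic) 1L else 2L }
         else { if (u < p_deterministic) 2L else 1L }
    for (j in seq_len(nf)) {
      state$counts[[j]][codes[i, j], k] <- state$counts[[j]][codes[i, j], k] + 1L
    }
    state$totals[k] <- state$totals[k] + 1L
    dA[i] <- a; dB[i] <- b; draws[i] <- u; arm_i[i] <- k
  }
  log <- data.frame(imbalance_control = dA, imbalance_intervention = dB,
                    draw = draws, arm = state$arms[arm_i])
  log <- cbind(
    sequence = seq_len(n),
    participant_id = if ("participant_id" %in% names(profiles))
      profiles$participant_id else seq_len(n),
    profiles[names(factors)], log)
  rownames(log) <- NULL
  attr(log, "state") <- state
  log
}

max_marginal_imbalance <- function(state) {
  max(vapply(state$counts, function(m) max(abs(m[, 1L] - m[, 2L])), numeric(1)))
}

sample_profiles <- function(n, freqs) {
  as.data.frame(lapply(freqs, function(p) {
    sample(names(p), n, replace = TRUE, prob = p)
  }), stringsAsFactors = FALSE)
}

#' Quantify balance gained by minimization over simple randomization
#'
#' Simulates paired trials: for each replicate one stream of participant
#' profiles is allocated both by minimization (with the given
#' `p_deterministic`) and by simple 1:1 randomization, and the maximum
#' absolute per-level arm difference and the arm-size difference are
#' recorded for both schemes.
#'
#' @param freqs named list: for each factor, a named probability vector
#'   over its levels (each summing to 1).
#' @param n participants per replicate.
#' @param p_deterministic minimization mixing weight.
#' @param replicates number of simulated trials.
#' @param seed RNG seed.
#' @return data.frame with one row per replicate: `max_imbalance_min`,
#'   `max_imbalance_simple`, `arm_diff_min`, `arm_diff_simple`.
#' @export
simulate_balance <- function(freqs, n, p_deterministic = 0.8,
                             replicates = 100, seed = NULL) {
  for (f in names(freqs)) {
    if (abs(sum(freqs[[f]]) - 1) > 1e-8) stop("frequencies for '", f, "' do not sum to 1")
  }
  if (!is.null(seed)) set.seed(seed)
  factors <- lapply(freqs, names)
  out <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    prof <- sample_profiles(n, freqs)
    log <- minimize_allocate(prof, p_deterministic, factors = factors)
    st_min <- attr(log, "state")
    # simple randomization on the same participant stream
    arm_simple <- sample(c("control", "intervention"), n, replace = TRUE)
    st_simple <- allocation_state(factors)
    for (i in seq_len(n)) {
      st_simple <- update_state(st_simple, as.list(prof[i, , drop = FALSE]), arm_simple[i])
    }
    out[[r]] <- data.frame(
      max_imbalance_min = max_marginal_imbalance(st_min),
      max_imbalance_simple = max_marginal_imbalance(st_simple),
      arm_diff_min = abs(diff(unname(st_min$totals))),
      arm_diff_simple = abs(diff(unname(st_simple$totals))))
  }
  do.call(rbind, out)
}

#' Factor level frequencies matching the reference cohort
#'
#' Approximate marginal frequencies of the five stratification factors in
#' a long-COVID weight-management cohort: fatigue is the dominant chosen
#' symptom (54%), the cohort is mostly female (85%) and white (90%), about
#' two-thirds are under 50, and deprivation bands split roughly evenly.
#' @return named list of named probability vectors.
#' @export
cohort_frequencies <- function() {
  list(
    chosen_symptom = c(fatigue = 0.54, breathlessness = 0.16, pain = 0.12,
                       anxiety_depression = 0.01, other = 0.17),
    sex = c(female = 0.85, male = 0.142, other = 0.008),
    age_band = c("<50" = 0.65, "50+" = 0.35),
    ethnicity = c(white = 0.90, south_asian = 0.04, other = 0.06),
    imd_band = c("1-5" = 0.53, "6-10" = 0.47)
  )
}
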
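#' @keywords internal
"_PACKAGE"

#' @importFrom stats anova as.formula binomial coef complete.cases
#'   delete.response glm lm model.matrix na.omit plogis pnorm predict pt
#'   qnorm qt quantile rbinom rchisq relevel residuals rnorm rpois runif
#'   sd setNames terms uniroot var vcov
#' @importFrom utils head read.csv write.csv packageVersion
NULL

# ---------------------------------------------------------------------------
# Instrument battery: Chalder fatigue scale (11 items), HADS (7 anxiety +
# 7 depression items), P4 pain (4 items), MRC dyspnea (single grade 1-5),
# symptom visual analog scales (0-10), EQ-5D (VAS 0-100, utility <= 1).
# All instruments are oriented so that higher = worse.
# ---------------------------------------------------------------------------

check_items <- function(items, n_items, lo, hi, what) {
  if (is.vector(items) && !is.matrix(items)) items <- matrix(items, nrow = 1L)
  items <- as.matrix(items)
  if (ncol(items) != n_items) {
    stop(sprintf("%s requires exactly %d items, got %d", what, n_items, ncol(items)),
         call. = FALSE)
  }
  complete <- stats::complete.cases(items)
  bad <- which(complete & apply(items, 1L, function(r) {
    any(r < lo | r > hi | r != trunc(r))
  }))
  if (length(bad)) {
    r <- bad[1L]
    j <- which(items[r, ] < lo | items[r, ] > hi | items[r, ] != trunc(items[r, ]))[1L]
    stop(sprintf("%s: item %d out of range [%d, %d] (row %d, value %s)",
                 what, j, lo, hi, r, format(items[r, j])), call. = FALSE)
  }
  items
}

#' Score the Chalder fatigue scale
#'
#' Scores the 11-item Chalder fatigue questionnaire. The default Likert
#' method scores each item 0-3 (total 0-33); the physical subscale is the
#' sum of items 1-7 (0-21) and the mental subscale the sum of items 8-11
#' (0-12). The bimodal method (each item dichotomized 0/0/1/1, total 0-11)
#' is provided for completeness but is not used by the pipeline.
#'
#' @param items numeric vector of length 11, or a matrix with 11 columns
#'   (one row per response set), each entry an integer in 0-3.
#' @param method `"likert"` (default) or `"bimodal"`.
#' @return data.frame with columns `total`, `physical`, `mental`. Rows with
#'   any missing item score as `NA` (no proration).
#' @examples
#' score_chalder(rep(3, 11)) # total 33
#' @export
score_chalder <- function(items, method = c("likert", "bimodal")) {
  method <- match.arg(method)
  items <- check_items(items, 11L, 0L, 3L, "chalder")
  if (method == "bimodal") items[] <- as.numeric(items >= 2)
  physical <- rowSums(items[, 1:7, drop = FALSE])
  mental <- rowSums(items[, 8:11, drop = FALSE])
  data.frame(total = physical + mental, physical = physical, mental = mental)
}

#' Score the hospital anxiety and depression scale (HADS)
#'
#' @param anxiety numeric vector of length 7 or matrix with 7 columns;
#'   anxiety items, each 0-3.
#' @param depression as `anxiety`, for the 7 depression items.
#' @return data.frame with columns `anxiety` (0-21), `depression` (0-21)
#'   and `total` (0-42). Any missing item makes the affected subscale and
#'   the total `NA`.
#' @export
score_hads <- function(anxiety, depression) {
  a <- check_items(anxiety, 7L, 0L, 3L, "hads anxiety")
  d <- check_items(depression, 7L, 0L, 3L, "hads depression")
  if (nrow(a) != nrow(d)) stop("anxiety and depression item sets differ in length")
  anx <- rowSums(a)
  dep <- rowSums(d)
  data.frame(anxiety = anx, depression = dep, total = anx + dep)
}

#' Score the P4 pain rating scale
#'
#' Sum of four 0-10 ratings (pain in the morning, afternoon, evening and
#' with activity), range 0-40.
#'
#' @param items numeric vector of length 4 or matrix with 4 columns.
#' @return numeric vector of totals (NA where any item is missing).
#' @export
score_p4 <- function(items) {
  items <- check_items(items, 4L, 0L, 10L, "p4")
  rowSums(items)
}

#' Normalize a free-text symptom label
#'
#' Lower-cases, trims, and collapses internal whitespace so that the same
#' symptom reported with different capitalization or spacing maps to one
#' label key across visits.
#'
#' @param label character vector.
#' @return normalized character vector.
#' @export
normalize_symptom_label <- function(label) {
  out <- tolower(trimws(as.character(label)))
  gsub("[[:space:]]+", " ", out)
}

core_symptoms <- function() c("fatigue", "breathlessness", "pain", "anxiety_depression")
all_symptoms <- function() c(core_symptoms(), "other")

instrument_ranges <- function() {
  list(chalder = c(0, 33), mrc_dyspnea = c(1, 5), p4 = c(0, 40),
       hads = c(0, 42), vas = c(0, 10), eq5d_vas = c(0, 100))
}

#' Column dictionary for the long-format visit table
#'
#' Names and descriptions of the columns expected in the main participant-
#' visit CSV and the companion other-symptom CSV.
#'
#' @return data.frame with columns `column`, `table`, `description`.
#' @export
visit_schema <- function() {
  main <- c(
    participant_id = "participant identifier",
    visit_month = "scheduled visit, months from randomization (0/3/6/12)",
    arm = "randomized arm (control/intervention)",
    chosen_symptom = "dominant symptom chosen at baseline",
    mrc_dyspnea = "MRC dyspnea grade 1-5",
    eq5d_vas = "EQ-5D visual analog scale 0-100",
    eq5d_utility = "EQ-5D health-state utility (<= 1)",
    weight_kg = "self-measured weight, kg",
    sbp_mmhg = "systolic blood pressure, mmHg",
    dbp_mmhg = "diastolic blood pressure, mmHg",
    work_hours_missed = "hours of work missed in past week (>= 0)"
  )
  items <- c(sprintf("chalder_%02d", 1:11), sprintf("hads_a%d", 1:7),
             sprintf("hads_d%d", 1:7), sprintf("p4_%d", 1:4))
  other <- c(participant_id = "participant identifier",
             visit_month = "scheduled visit month",
             symptom_label = "normalized free-text symptom label",
             vas = "10-point visual analog rating")
  rbind(
    data.frame(column = c(names(main), items), table = "main",
               description = c(unname(main), rep("instrument item", length(items)))),
    data.frame(column = names(other), table = "other", description = unname(other))
  )
}

#' Validate a long-format visit table
#'
#' Checks every present instrument against its invariants, appends derived
#' instrument totals, and leaves missing instruments missing (never zero).
#' Unknown columns are kept but reported with a warning. Validation is
#' idempotent: re-validating a validated table returns the same table.
#'
#' @param visits data.frame, one row per participant-visit, columns per
#'   [visit_schema()].
#' @param other optional data.frame of other-symptom VAS ratings
#'   (`participant_id`, `visit_month`, `symptom_label`, `vas`); labels are
#'   case/whitespace-normalized.
#' @return list with `visits` (input plus `chalder_total`, `chalder_physical`,
#'   `chalder_mental`, `hads_anxiety`, `hads_depression`, `hads_total`,
#'   `p4_total`) and `other` (normalized, or NULL).
#' @export
validate_visits <- function(visits, other = NULL) {
  stopifnot(is.data.frame(visits))
  need <- c("participant_id", "visit_month")
  miss <- setdiff(need, names(visits))
  if (length(miss)) stop("visit table lacks required columns: ", paste(miss, collapse = ", "))
  if (!all(visits$visit_month %in% c(0, 3, 6, 12))) {
    stop("visit_month must be one of 0, 3, 6, 12")
  }
  known <- c(visit_schema()$column[visit_schema()$table == "main"],
             "sex", "age", "age_band", "ethnicity", "imd_band", "bmi",
             "education", "physical_activity", "employment_change",
             "main_other_symptom", "chalder_total", "chalder_physical",
             "chalder_mental", "hads_anxiety", "hads_depression",
             "hads_total", "p4_total")
  unknown <- setdiff(names(visits), known)
  if (length(unknown)) {
    warning("ignoring unknown columns: ", paste(unknown, collapse = ", "))
  }

  chalder_cols <- sprintf("chalder_%02d", 1:11)
  if (all(chalder_cols %in% names(visits))) {
    sc <- score_chalder(as.matrix(visits[chalder_cols]))
    visits$chalder_total <- sc$total
    visits$chalder_physical <- sc$physical
    visits$chalder_mental <- sc$mental
  }
  ha <- sprintf("hads_a%d", 1:7); hd <- sprintf("hads_d%d", 1:7)
  if (all(c(ha, hd) %in% names(visits))) {
    sh <- score_hads(as.matrix(visits[ha]), as.matrix(visits[hd]))
    visits$hads_anxiety <- sh$anxiety
    visits$hads_depression <- sh$depression
    visits$hads_total <- sh$total
  }
  p4c <- sprintf("p4_%d", 1:4)
  if (all(p4c %in% names(visits))) {
    visits$p4_total <- score_p4(as.matrix(visits[p4c]))
  }
  if ("mrc_dyspnea" %in% names(visits)) {
    g <- visits$mrc_dyspnea
    bad <- which(!is.na(g) & (g < 1 | g > 5 | g != trunc(g)))
    if (length(bad)) {
      stop(sprintf("mrc_dyspnea out of range 1-5 at row %d (value %s)",
                   bad[1L], format(g[bad[1L]])))
    }
  }
  bounds <- list(eq5d_vas = c(0, 100), vas = c(0, 10))
  if ("eq5d_vas" %in% names(visits)) {
    v <- visits$eq5d_vas
    if (any(!is.na(v) & (v < 0 | v > 100))) stop("eq5d_vas outside [0, 100]")
  }
  if ("eq5d_utility" %in% names(visits)) {
    u <- visits$eq5d_utility
    if (any(!is.na(u) & u > 1)) stop("eq5d_utility above 1")
  }
  if ("work_hours_missed" %in% names(visits)) {
    w <- visits$work_hours_missed
    if (any(!is.na(w) & w < 0)) stop("work_hours_missed must be >= 0")
  }

  if (!is.null(other)) {
    stopifnot(all(c("participant_id", "visit_month", "symptom_label", "vas") %in% names(other)))
    other$symptom_label <- normalize_symptom_label(other$symptom_label)
    if (any(!nzchar(other$symptom_label))) stop("empty symptom label in other-symptom table")
    if (any(!is.na(other$vas) & (other$vas < 0 | other$vas > 10))) {
      stop("other-symptom vas outside [0, 10]")
    }
  }
  list(visits = visits, other = other)
}
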
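# ---------------------------------------------------------------------------
# Respective primary outcome: each participant nominates at baseline the
# symptom they most want improved; that symptom's instrument score,
# standardized by the baseline mean and s.d. of the subgroup nominating the
# same symptom, is the common-scale primary outcome at every visit.
# Lower is better for every feeding instrument, so negative change over
# time means improvement.
# ---------------------------------------------------------------------------

chosen_instrument_column <- function(symptom) {
  c(fatigue = "chalder_total", breathlessness = "mrc_dyspnea",
    pain = "p4_total", anxiety_depression = "hads_total")[symptom]
}

#' Extract each participant's chosen-symptom raw score at each visit
#'
#' For the four core symptoms the relevant instrument total is used
#' (Chalder total for fatigue, MRC grade for breathlessness, P4 total for
#' pain, HADS total for anxiety/depression). For an "other" chooser the VAS
#' rating of the specific main symptom identified at baseline is tracked
#' across visits. A score is missing when the instrument (or label) is
#' absent at that visit.
#'
#' @param cohort data.frame with one row per participant: `participant_id`,
#'   `chosen_symptom`, and `main_other_symptom` for "other" choosers.
#' @param visits validated visit table (see [validate_visits()]).
#' @param other other-symptom VAS table (required if any "other" choosers).
#' @return data.frame `participant_id`, `visit_month`, `chosen_symptom`,
#'   `raw_score` (NA when unavailable).
#' @export
extract_chosen_raw <- function(cohort, visits, other = NULL) {
  stopifnot(all(c("participant_id", "chosen_symptom") %in% names(cohort)))
  bad <- setdiff(unique(cohort$chosen_symptom), all_symptoms())
  if (length(bad)) stop("unknown chosen_symptom level(s): ", paste(bad, collapse = ", "))
  is_other <- cohort$chosen_symptom == "other"
  if (any(is_other)) {
    if (!"main_other_symptom" %in% names(cohort) ||
        any(is.na(cohort$main_other_symptom[is_other]) |
            !nzchar(cohort$main_other_symptom[is_other]))) {
      stop("'other' choosers must carry a baseline main_other_symptom label")
    }
    if (is.null(other)) stop("other-symptom table required when 'other' choosers are present")
  }

  out <- merge(visits[c("participant_id", "visit_month")],
               cohort[c("participant_id", "chosen_symptom")],
               by = "participant_id")
  out <- out[order(out$participant_id, out$visit_month), , drop = FALSE]
  rownames(out) <- NULL
  key <- paste(out$participant_id, out$visit_month)
  vkey <- paste(visits$participant_id, visits$visit_month)
  out$raw_score <- NA_real_
  for (sym in core_symptoms()) {
    sel <- out$chosen_symptom == sym
    if (!any(sel)) next
    col <- chosen_instrument_column(sym)
    if (!col %in% names(visits)) {
      stop("visit table lacks column '", col, "' needed for symptom '", sym, "'")
    }
    out$raw_score[sel] <- visits[[col]][match(key[sel], vkey)]
  }
  sel <- out$chosen_symptom == "other"
  if (any(sel)) {
    lab <- normalize_symptom_label(
      cohort$main_other_symptom[match(out$participant_id[sel], cohort$participant_id)])
    okey <- paste(other$participant_id, other$visit_month,
                  normalize_symptom_label(other$symptom_label))
    out$raw_score[sel] <- other$vas[match(paste(key[sel], lab), okey)]
  }
  out
}

#' Fit baseline standardization references per chosen-symptom subgroup
#'
#' For each core symptom the reference is the mean and sample s.d.
#' (n-1 denominator) of the baseline chosen-symptom scores of all
#' randomized participants -- both arms -- who chose that symptom. For the
#' "other" stratum the default pools the baseline VAS ratings of all
#' "other" choosers' main symptoms into a single reference (the labels
#' share the 0-10 scale and are individually too sparse); `per_label = TRUE`
#' instead fits one reference per main-symptom label.
#'
#' @param cohort,visits,other as [extract_chosen_raw()].
#' @param per_label fit per-label references for the "other" stratum.
#' @param on_degenerate what to do with a subgroup with fewer than 2
#'   baseline scores or zero s.d.: `"error"` (default) or `"drop"` (omit
#'   the reference; participants in that stratum get no standardized score).
#' @return data.frame `symptom`, `label` (NA except per-label mode), `n`,
#'   `baseline_mean`, `baseline_sd`, of class `respectr_references`.
#' @export
fit_references <- function(cohort, visits, other = NULL, per_label = FALSE,
                           on_degenerate = c("error", "drop")) {
  on_degenerate <- match.arg(on_degenerate)
  raw <- extract_chosen_raw(cohort, visits, other)
  raw <- raw[raw$visit_month == 0, , drop = FALSE]
  if (any(is.na(raw$raw_score))) {
    stop("missing baseline chosen-symptom score for participant(s): ",
         paste(utils::head(raw$participant_id[is.na(raw$raw_score)], 5L), collapse = ", "))
  }
  if (per_label) {
    lab <- ifelse(raw$chosen_symptom == "other",
                  normalize_symptom_label(cohort$main_other_symptom[
                    match(raw$participant_id, cohort$participant_id)]),
                  NA_character_)
    grp <- ifelse(is.na(lab), raw$chosen_symptom, paste0("other:", lab))
  } else {
    lab <- rep(NA_character_, nrow(raw))
    grp <- raw$chosen_symptom
  }
  agg <- split(seq_len(nrow(raw)), grp)
  refs <- do.call(rbind, lapply(names(agg), function(g) {
    i <- agg[[g]]
    data.frame(symptom = sub(":.*$", "", g),
               label = if (grepl("^other:", g)) sub("^other:", "", g) else NA_character_,
               n = length(i),
               baseline_mean = mean(raw$raw_score[i]),
               baseline_sd = stats::sd(raw$raw_score[i]))
  }))
  degenerate <- refs$n < 2 | is.na(refs$baseline_sd) | refs$baseline_sd <= 0
  if (any(degenerate)) {
    msg <- paste0(refs$symptom[degenerate],
                  ifelse(is.na(refs$label[degenerate]), "", paste0(":", refs$label[degenerate])),
                  " (n=", refs$n[degenerate], ", sd=",
                  signif(refs$baseline_sd[degenerate], 3), ")")
    if (on_degenerate == "error") {
      stop("degenerate standardization reference for subgroup(s): ",
           paste(msg, collapse = "; "),
           "; a finite reference needs n >= 2 and positive s.d.")
    }
    warning("dropping degenerate reference(s): ", paste(msg, collapse = "; "))
    refs <- refs[!degenerate, , drop = FALSE]
  }
  rownames(refs) <- NULL
  class(refs) <- c("respectr_references", class(refs))
  attr(refs, "per_label") <- per_label
  refs
}

#' Standardize a raw chosen-symptom score against a baseline reference
#'
#' `z = (raw - baseline_mean) / baseline_sd`. The same baseline reference
#' is applied at every visit, so follow-up z values are changes measured
#' in baseline-s.d. units of the participant's own subgroup.
#'
#' @param raw numeric vector of raw scores.
#' @param baseline_mean,baseline_sd reference parameters (`baseline_sd > 0`).
#' @return numeric vector of standardized scores.
#' @export
standardize_score <- function(raw, baseline_mean, baseline_sd) {
  if (any(!is.finite(baseline_sd)) || any(baseline_sd <= 0)) {
    stop("baseline_sd must be finite and positive")
  }
  (raw - baseline_mean) / baseline_sd
}

#' Build the respective primary outcome table
#'
#' Joins every participant-visit chosen-symptom raw score with its
#' subgroup's baseline reference and standardizes. By construction the
#' baseline mean over all randomized participants is 0 and each subgroup's
#' baseline s.d. is exactly 1 (n-1 convention).
#'
#' @param cohort,visits,other as [extract_chosen_raw()].
#' @param refs optional precomputed [fit_references()] output; fitted from
#'   the baseline visit when NULL.
#' @param ... passed to [fit_references()] when `refs` is NULL.
#' @return data.frame `participant_id`, `visit_month`, `chosen_symptom`,
#'   `raw_score`, `z`; attribute `"references"` holds the references used.
#' @export
build_primary_outcome <- function(cohort, visits, other = NULL, refs = NULL, ...) {
  if (is.null(refs)) refs <- fit_references(cohort, visits, other, ...)
  raw <- extract_chosen_raw(cohort, visits, other)
  if (isTRUE(attr(refs, "per_label"))) {
    lab <- ifelse(raw$chosen_symptom == "other",
                  normalize_symptom_label(cohort$main_other_symptom[
                    match(raw$participant_id, cohort$participant_id)]),
                  NA_character_)
    i <- match(paste(raw$chosen_symptom, lab), paste(refs$symptom, refs$label))
  } else {
    i <- match(raw$chosen_symptom, refs$symptom)
  }
  raw$z <- standardize_score(raw$raw_score, refs$baseline_mean[i], refs$baseline_sd[i])
  raw <- raw[!is.na(raw$raw_score), , drop = FALSE]
  rownames(raw) <- NULL
  attr(raw, "references") <- refs
  raw
}

#' Recode "other" symptom choices onto core symptoms (sensitivity dataset)
#'
#' Applies a label -> core-symptom map to "other" choosers whose free-text
#' main symptom matches a core symptom (e.g. "fatigued" -> fatigue). The
#' returned cohort has those participants' `chosen_symptom` replaced;
#' references must then be refitted on the recoded cohort (done by
#' [build_primary_outcome()] when given the recoded cohort).
#'
#' @param cohort cohort table.
#' @param map named character vector: names are normalized other-symptom
#'   labels, values are core symptom levels.
#' @return recoded cohort.
#' @export
apply_recode <- function(cohort, map) {
  if (length(map) == 0) return(cohort)
  if (is.null(names(map)) || any(!nzchar(names(map)))) {
    stop("recode map must be a named character vector (label -> core symptom)")
  }
  bad <- setdiff(unname(map), core_symptoms())
  if (length(bad)) {
    stop("recode targets must be core symptoms; offending: ", paste(bad, collapse = ", "))
  }
  names(map) <- normalize_symptom_label(names(map))
  sel <- cohort$chosen_symptom == "other" &
    normalize_symptom_label(cohort$main_other_symptom) %in% names(map)
  cohort$chosen_symptom[sel] <-
    unname(map[normalize_symptom_label(cohort$main_other_symptom[sel])])
  cohort
}
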
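# Cohort table schema: one row per assessed subject, holding subscale
# ratings for one or both instruments plus the shared clinical facts both
# rule engines consume (course, trait risk, functioning history).

caarms_rating_cols <- c(
  paste0("caarms_p", 1:4, "_severity"),
  paste0("caarms_p", 1:4, "_frequency"),
  paste0("caarms_p", 1:4, "_substance"),
  paste0("caarms_p", 1:4, "_distress")
)

sips_rating_cols <- c(
  paste0("sips_p", 1:5, "_severity"),
  paste0("sips_p", 1:5, "_frequency"),
  paste0("sips_p", 1:5, "_substance_intertwined")
)

functioning_cols <- c(
  "sofas_current", "sofas_premorbid",
  "sofas_drop_sustained_1m_12m", "sofas_below_50_12m",
  "gaf_current_month", "gaf_12_months_ago"
)

trait_cols <- c("schizotypal_pd", "family_history_psychosis")

course_cols <- c(
  "onset_months_ago", "symptoms_gt_5y", "severity_increased_past_year",
  "present_past_month", "psychotic_duration_days", "psychotic_onset_months_ago",
  "resolved_without_antipsychotics", "danger_or_disorganization",
  "substance_peak_only", "comorbid_better_explains", "prior_psychotic_episode"
)

cohort_bool_cols <- c(
  paste0("sips_p", 1:5, "_substance_intertwined"),
  "sofas_drop_sustained_1m_12m", "sofas_below_50_12m",
  trait_cols,
  "symptoms_gt_5y", "severity_increased_past_year", "present_past_month",
  "resolved_without_antipsychotics", "danger_or_disorganization",
  "substance_peak_only", "comorbid_better_explains", "prior_psychotic_episode"
)

#' Column names of the cohort table schema
#'
#' The tabular schema used for subject records throughout the package: one
#' row per subject, `subject_id` plus CAARMS 12/2006 ratings (severity,
#' frequency, substance-relation code 0-2 and optional distress 0-100 for
#' subscales P1-P4), SIPS 5.0 ratings (severity 0-6, frequency 0-3 and a
#' per-subscale substance-intertwined flag for P1-P5), functioning history
#' (SOFAS and GAF), trait risk, and the shared clinical-course flags. Boolean
#' columns are encoded 0/1 on disk; an empty cell means "unknown".
#'
#' @return Character vector of column names.
#' @export
#' @examples
#' cohort_columns()
cohort_columns <- function() {
  c("subject_id", caarms_rating_cols, sips_rating_cols,
    functioning_cols, trait_cols, course_cols)
}

#' Create an empty (or partially filled) cohort table
#'
#' Returns a tibble with the full cohort schema, one row per element of
#' `subject_id`, all other fields `NA` ("unknown"). Useful as a template for
#' building records programmatically; fill in whichever instrument(s) were
#' rated.
#'
#' @param subject_id Character vector of subject identifiers.
#' @param ... Named schema columns to set, recycled to the number of rows.
#' @return A tibble with columns [cohort_columns()].
#' @export
#' @examples
#' blank_cohort("s1", caarms_p1_severity = 4, caarms_p1_frequency = 4)
blank_cohort <- function(subject_id = character(), ...) {
  n <- length(subject_id)
  out <- tibble::tibble(subject_id = as.character(subject_id))
  for (col in setdiff(cohort_columns(), "subject_id")) {
    out[[col]] <- if (col %in% cohort_bool_cols) rep(NA, n) else rep(NA_real_, n)
  }
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), cohort_columns())
    if (length(bad)) stop("unknown cohort columns: ", paste(bad, collapse = ", "))
    for (nm in names(dots)) out[[nm]] <- rep_len(dots[[nm]], n)
  }
  out
}

has_caarms <- function(cohort) {
  sev <- as.matrix(cohort[paste0("caarms_p", 1:4, "_severity")])
  rowSums(!is.na(sev)) > 0
}

has_sips <- function(cohort) {
  sev <- as.matrix(cohort[paste0("sips_p", 1:5, "_severity")])
  rowSums(!is.na(sev)) > 0
}

#' Validate a cohort table against the instrument data model
#'
#' Checks every row against the rating-scale invariants: CAARMS severities
#' and frequencies in 0-6, substance codes in 0-2, distress in 0-100; SIPS
#' severities in 0-6 and frequencies in 0-3; SOFAS/GAF scores in 0-100;
#' nonnegative durations; duration consistent with elapsed time since
#' psychotic onset; and at least one instrument rated. Validation reports,
#' it never throws: the result is a tibble of violations (empty when the
#' cohort is valid), one row per violated rule naming the subject, row,
#' field and rule.
#'
#' @param cohort A data frame in the cohort schema (see [cohort_columns()]).
#' @return A tibble with columns `row`, `subject_id`, `field`, `rule`.
#' @export
#' @examples
#' bad <- blank_cohort("s1", caarms_p1_severity = 7)
#' validate_cohort(bad)
validate_cohort <- function(cohort) {
  cohort <- as_tibble(cohort)
  out <- list()
  add <- function(idx, field, rule) {
    if (any(idx)) {
      out[[length(out) + 1L]] <<- tibble(
        row = which(idx),
        subject_id = as.character(cohort$subject_id[idx]),
        field = field, rule = rule)
    }
  }
  range_check <- function(col, lo, hi, rule) {
    x <- cohort[[col]]
    add(!is.na(x) & (x < lo | x > hi | x != round(x)), col, rule)
  }
  for (i in 1:4) {
    range_check(paste0("caarms_p", i, "_severity"), 0, 6, "severity out of [0,6]")
    range_check(paste0("caarms_p", i, "_frequency"), 0, 6, "frequency out of [0,6]")
    range_check(paste0("caarms_p", i, "_substance"), 0, 2, "substance code out of [0,2]")
    range_check(paste0("caarms_p", i, "_distress"), 0, 100, "distress out of [0,100]")
  }
  for (i in 1:5) {
    range_check(paste0("sips_p", i, "_severity"), 0, 6, "severity out of [0,6]")
    range_check(paste0("sips_p", i, "_frequency"), 0, 3, "frequency out of [0,3]")
  }
  for (col in c("sofas_current", "sofas_premorbid", "gaf_current_month",
                "gaf_12_months_ago")) {
    x <- cohort[[col]]
    add(!is.na(x) & (x < 0 | x > 100), col, "score out of [0,100]")
  }
  for (col in c("onset_months_ago", "psychotic_duration_days",
                "psychotic_onset_months_ago")) {
    x <- cohort[[col]]
    add(!is.na(x) & x < 0, col, "negative duration")
  }
  dur <- cohort$psychotic_duration_days
  ons <- cohort$psychotic_onset_months_ago
  add(!is.na(dur) & !is.na(ons) & dur > ons * DAYS_PER_MONTH + DAYS_PER_MONTH,
      "psychotic_duration_days",
      "duration exceeds elapsed time since psychotic onset")
  add(!has_caarms(cohort) & !has_sips(cohort), "subject_id",
      "no instrument rated")
  if (length(out) == 0) {
    tibble(row = integer(), subject_id = character(),
           field = character(), rule = character())
  } else {
    arrange(bind_rows(out), row, field)
  }
}

#' CAARMS functioning (SOFAS deterioration) criterion
#'
#' The CAARMS 12/2006 level-of-functioning gate required by all three UHR
#' subgroups: a 30% drop in SOFAS from the premorbid level, sustained for a
#' month within the past 12 months, OR a SOFAS score below 50 for the past
#' 12 months or more. The 30% drop is operationalized inclusively as
#' `current <= 0.70 * premorbid` on the raw 0-100 scale. A zero or missing
#' premorbid score makes the drop disjunct false (with a warning for zero:
#' a proportional drop from 0 is undefined).
#'
#' @param sofas_current,sofas_premorbid Current and premorbid SOFAS (0-100).
#' @param drop_sustained Logical: was the drop sustained for a month within
#'   the past 12 months?
#' @param below_50_12m Logical: SOFAS < 50 for the past 12 months or more?
#' @return Logical vector.
#' @export
#' @examples
#' functioning_criterion_caarms(55, 80, TRUE, FALSE)  # TRUE: 55 <= 0.7 * 80
#' functioning_criterion_caarms(60, 80, TRUE, FALSE)  # FALSE
#' functioning_criterion_caarms(48, NA, FALSE, TRUE)  # TRUE via second disjunct
functioning_criterion_caarms <- function(sofas_current, sofas_premorbid,
                                         drop_sustained, below_50_12m) {
  n <- max(length(sofas_current), length(sofas_premorbid),
           length(drop_sustained), length(below_50_12m))
  sofas_current <- rep_len(sofas_current, n)
  sofas_premorbid <- rep_len(sofas_premorbid, n)
  drop_sustained <- rep_len(drop_sustained, n)
  below_50_12m <- rep_len(below_50_12m, n)
  if (any(!is.na(sofas_premorbid) & sofas_premorbid == 0)) {
    warning("premorbid SOFAS of 0: proportional drop undefined, treated as not met")
  }
  drop_ok <- !is.na(sofas_current) & !is.na(sofas_premorbid) &
    sofas_premorbid > 0 & sofas_current <= 0.70 * sofas_premorbid
  (drop_ok & flag(drop_sustained)) | flag(below_50_12m)
}

#' SIPS GRD functioning (GAF drop) criterion
#'
#' The SIPS 5.0 genetic-risk-and-deterioration functioning gate: a 30% drop
#' in GAF over the last month compared with 12 months before, operationalized
#' inclusively as `current <= 0.70 * reference`. A zero reference GAF makes
#' the criterion false with a warning.
#'
#' @param gaf_current_month Mean GAF over the last month (0-100).
#' @param gaf_12_months_ago GAF 12 months before (0-100).
#' @return Logical vector.
#' @export
#' @examples
#' functioning_criterion_sips_grd(49, 70)  # TRUE: 49 = 0.7 * 70
#' functioning_criterion_sips_grd(50, 70)  # FALSE
functioning_criterion_sips_grd <- function(gaf_current_month, gaf_12_months_ago) {
  n <- max(length(gaf_current_month), length(gaf_12_months_ago))
  gaf_current_month <- rep_len(gaf_current_month, n)
  gaf_12_months_ago <- rep_len(gaf_12_months_ago, n)
  if (any(!is.na(gaf_12_months_ago) & gaf_12_months_ago == 0)) {
    warning("reference GAF of 0: proportional drop undefined, treated as not met")
  }
  !is.na(gaf_current_month) & !is.na(gaf_12_months_ago) &
    gaf_12_months_ago > 0 & gaf_current_month <= 0.70 * gaf_12_months_ago
}
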
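# CAARMS 12/2006 diagnostic rule engine.
#
# Criterion bands (positive subscales P1 Unusual Thought Content, P2
# Non-Bizarre Ideas, P3 Perceptual Abnormalities, P4 Disorganized Speech):
#   attenuated severity: P1 3-5, P2 3-5, P3 3-4, P4 4-5
#   psychotic severity:  P1 6, P2 6, P3 5-6, P4 6
#   APS subthreshold-intensity frequency: 3-6; subthreshold-frequency: exactly 3
#   BLIPS / Psychosis frequency: 4-6; BLIPS duration cap 7 days
#   onset window 12 months, maximum symptom age 5 years
caarms_attenuated_lo <- c(3, 3, 3, 4)
caarms_attenuated_hi <- c(5, 5, 4, 5)
caarms_psychotic_lo <- c(6, 6, 5, 6)

#' Subscales at CAARMS psychotic intensity
#'
#' Returns, per subject, the CAARMS subscales whose severity reaches the
#' psychotic band (6 on P1, P2 or P4; 5-6 on P3).
#'
#' @param cohort A data frame in the cohort schema with CAARMS ratings.
#' @return A list (one element per row) of subscale names, e.g. `c("P1","P3")`.
#' @export
#' @examples
#' psychotic_intensity_caarms(blank_cohort("a", caarms_p3_severity = 5))
psychotic_intensity_caarms <- function(cohort) {
  sev <- as.matrix(cohort[paste0("caarms_p", 1:4, "_severity")])
  apply(sev, 1, function(s) {
    s[is.na(s)] <- 0
    caarms_subscales[s >= caarms_psychotic_lo]
  }, simplify = FALSE)
}

# classify one subject; x is a one-row list of schema fields
classify_caarms_one <- function(x) {
  sev <- vapply(paste0("caarms_p", 1:4, "_severity"), function(c) as.numeric(x[[c]]), 0)
  frq <- vapply(paste0("caarms_p", 1:4, "_frequency"), function(c) as.numeric(x[[c]]), 0)
  notes <- character()
  if (anyNA(sev) || anyNA(frq)) notes <- c(notes, "missing CAARMS score treated as 0")
  sev[is.na(sev)] <- 0
  frq[is.na(frq)] <- 0

  psych <- sev >= caarms_psychotic_lo
  att <- sev >= caarms_attenuated_lo & sev <= caarms_attenuated_hi
  psych_paired <- psych & frq >= 4 & frq <= 6       # psychotic intensity + freq band
  aps_intensity <- att & frq >= 3 & frq <= 6        # subthreshold intensity path
  aps_frequency <- psych & frq == 3                 # subthreshold frequency path

  dur <- x$psychotic_duration_days
  if (any(psych_paired) && is.na(dur)) {
    notes <- c(notes, "unknown psychotic duration treated as 0 days")
    dur <- 0
  }
  resolved <- x$resolved_without_antipsychotics
  if (any(psych_paired) && is.na(resolved)) {
    notes <- c(notes, "unknown resolution assumed spontaneous")
  }

  fn <- functioning_criterion_caarms(
    x$sofas_current, x$sofas_premorbid,
    x$sofas_drop_sustained_1m_12m, x$sofas_below_50_12m)
  onset_ok <- !is.na(x$onset_months_ago) && x$onset_months_ago <= 12 &&
    !flag(x$symptoms_gt_5y)
  substance_ok <- !flag(x$substance_peak_only)

  trace <- list()
  tr <- function(id, pass) trace[[length(trace) + 1L]] <<- list(criterion = id, passed = pass)

  prior <- flag(x$prior_psychotic_episode)
  tr("prior_psychotic_episode", prior)
  tr("psychotic_intensity", any(psych))
  tr("psychotic_frequency_4_6", any(psych_paired))

  over_threshold <- any(psych_paired) &&
    (dur > CAARMS_BLIPS_MAX_DURATION_DAYS || !flag(resolved))
  tr("psychosis_duration_or_unresolved", over_threshold)

  if (prior || over_threshold) {
    return(result_row("CAARMS", "Psychosis", character(), trace, notes))
  }

  tr("onset_window_12m_le_5y", onset_ok)
  tr("functioning_sofas", fn)
  tr("substance_peak_only_exclusion", !substance_ok)

  blips <- any(psych_paired) && dur <= CAARMS_BLIPS_MAX_DURATION_DAYS &&
    flag(resolved) && onset_ok && fn && substance_ok
  tr("blips", blips)

  if (any(aps_frequency) && !any(aps_intensity)) {
    notes <- c(notes, "psychotic intensity at frequency 3: subthreshold-frequency APS path")
  }
  aps <- (any(aps_intensity) || any(aps_frequency)) && onset_ok && fn && substance_ok
  tr("aps", aps)

  grd <- (flag(x$schizotypal_pd) || flag(x$family_history_psychosis)) && fn
  tr("vulnerability_grd", grd)

  subgroups <- uhr_subgroup_levels[c(grd, aps, blips)]
  outcome <- if (length(subgroups)) "UHR+" else "UHR-"
  result_row("CAARMS", outcome, subgroups, trace, notes)
}

result_row <- function(instrument, outcome, subgroups, trace, notes) {
  trace_tbl <- if (length(trace)) {
    tibble(criterion = map_chr(trace, "criterion"),
           passed = map_lgl(trace, "passed"))
  } else {
    tibble(criterion = character(), passed = logical())
  }
  # primary subgroup label: BLIPS > APS > GRD
  primary <- if (length(subgroups)) {
    uhr_subgroup_levels[max(match(subgroups, uhr_subgroup_levels))]
  } else NA_character_
  list(instrument = instrument, outcome = outcome, subgroup = primary,
       subgroups_met = paste(subgroups, collapse = ";"),
       rule_trace = trace_tbl, notes = paste(notes, collapse = "; "))
}

assemble_results <- function(cohort, rows) {
  tibble(
    subject_id = as.character(cohort$subject_id),
    instrument = map_chr(rows, "instrument"),
    outcome = outcome_factor(map_chr(rows, "outcome")),
    subgroup = map_chr(rows, "subgroup"),
    subgroups_met = map_chr(rows, "subgroups_met"),
    rule_trace = map(rows, "rule_trace"),
    notes = map_chr(rows, "notes")
  )
}

#' Classify a cohort under the CAARMS 12/2006 criteria
#'
#' Applies the CAARMS 12/2006 diagnostic algorithm to each subject:
#' Psychosis threshold (psychotic-intensity severity with frequency 4-6
#' lasting more than 7 days or not resolving spontaneously, or a previous
#' psychotic episode), then the three UHR subgroups - BLIPS (psychotic
#' intensity, frequency 4-6, up to 7 days, spontaneous resolution), APS
#' (attenuated severity with frequency 3-6, or psychotic intensity at
#' frequency exactly 3), and Vulnerability/GRD (schizotypal personality
#' disorder or a first-degree relative with psychosis) - each gated by the
#' 12-month onset window, the 5-year maximum symptom age (BLIPS/APS), the
#' SOFAS functioning criterion (all subgroups) and the peak-intoxication
#' substance exclusion. Severity and qualifying frequency must be met on the
#' same subscale. All subgroups whose criteria pass are reported; the primary
#' subgroup label takes precedence BLIPS > APS > GRD.
#'
#' @param cohort A data frame in the cohort schema with CAARMS ratings.
#' @return A tibble with one row per subject: `subject_id`, `instrument`,
#'   `outcome` (ordered factor `UHR-` < `UHR+` < `Psychosis`), `subgroup`
#'   (primary label), `subgroups_met` (all met, `;`-separated), `rule_trace`
#'   (list-column of criterion/passed tibbles) and `notes` (assumptions made
#'   for unknown fields).
#' @export
#' @examples
#' x <- blank_cohort("s1",
#'   caarms_p1_severity = 4, caarms_p1_frequency = 4,
#'   onset_months_ago = 6, sofas_current = 50, sofas_premorbid = 80,
#'   sofas_drop_sustained_1m_12m = TRUE)
#' classify_caarms(x)
classify_caarms <- function(cohort) {
  cohort <- as_tibble(cohort)
  if (!all(has_caarms(cohort))) {
    stop("instrument not rated: CAARMS severities missing for subject(s) ",
         paste(head(cohort$subject_id[!has_caarms(cohort)]), collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    classify_caarms_one(as.list(cohort[i, ]))
  })
  assemble_results(cohort, rows)
}
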
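# SIPS 5.0 diagnostic rule engine.
#
# Positive subscales: P1 Unusual Thought Content/Delusional Ideas, P2
# Suspiciousness/Persecutory Ideas, P3 Grandiose Ideas, P4 Perceptual
# Abnormalities/Hallucinations, P5 Disorganized Communication.
# Bands: attenuated severity 3-5 on any subscale; psychotic severity 6.
# Qualifying frequency (0-3 scale): APS >= 2, BIPS >= 1, POPS exactly 3.
# BIPS: psychotic onset within 3 months, duration up to 3 months.
# Urgency: a seriously disorganizing or dangerous psychotic symptom is over
# the psychosis threshold no matter what the duration.

#' SIPS presence-of-psychotic-syndrome (POPS) threshold
#'
#' True when some subscale is at severity 6 with paired frequency 3
#' (at least one hour per day, at least four days per week over a month),
#' or at severity 6 with the urgency criterion (symptoms seriously
#' disorganizing and dangerous) regardless of frequency or duration.
#'
#' @param cohort A data frame in the cohort schema with SIPS ratings.
#' @return Logical vector, one element per row.
#' @export
#' @examples
#' pops_psychosis(blank_cohort("a", sips_p2_severity = 6, sips_p2_frequency = 3))
pops_psychosis <- function(cohort) {
  cohort <- as_tibble(cohort)
  sev <- as.matrix(cohort[paste0("sips_p", 1:5, "_severity")])
  frq <- as.matrix(cohort[paste0("sips_p", 1:5, "_frequency")])
  sev[is.na(sev)] <- 0
  frq[is.na(frq)] <- 0
  sustained <- rowSums(sev == 6 & frq == 3) > 0
  urgent <- rowSums(sev == 6) > 0 & flag(cohort$danger_or_disorganization)
  sustained | urgent
}

classify_sips_one <- function(x) {
  sev <- vapply(paste0("sips_p", 1:5, "_severity"), function(c) as.numeric(x[[c]]), 0)
  frq <- vapply(paste0("sips_p", 1:5, "_frequency"), function(c) as.numeric(x[[c]]), 0)
  sub <- vapply(paste0("sips_p", 1:5, "_substance_intertwined"),
                function(c) flag(x[[c]]), NA)
  notes <- character()
  if (anyNA(sev) || anyNA(frq)) notes <- c(notes, "missing SIPS score treated as 0")
  sev[is.na(sev)] <- 0
  frq[is.na(frq)] <- 0

  psych <- sev == 6
  att <- sev >= 3 & sev <= 5
  danger <- flag(x$danger_or_disorganization)

  trace <- list()
  tr <- function(id, pass) trace[[length(trace) + 1L]] <<- list(criterion = id, passed = pass)

  prior <- flag(x$prior_psychotic_episode)
  tr("prior_psychotic_episode", prior)
  pops <- any(psych & frq == 3) || (any(psych) && danger)
  tr("pops_severity6_frequency3_or_urgency", pops)
  if (any(psych) && danger) tr("urgency_disorganizing_dangerous", TRUE)

  if (prior || pops) {
    return(result_row("SIPS", "Psychosis", character(), trace, notes))
  }

  comorbid <- flag(x$comorbid_better_explains)
  tr("comorbid_better_explains_exclusion", comorbid)

  # BIPS: severity 6, paired frequency >= 1 (frequency 3 already caught by
  # POPS above), psychotic onset within 3 months, duration <= 3 months
  bips_sub <- psych & frq >= 1 & !sub
  if (any(psych & frq == 2 & !sub)) {
    notes <- c(notes, "severity 6 at frequency 2: qualifies BIPS band (below POPS)")
  }
  dur <- x$psychotic_duration_days
  if (any(bips_sub) && is.na(dur)) {
    notes <- c(notes, "unknown psychotic duration treated as 0 days")
    dur <- 0
  }
  bips_onset <- !is.na(x$psychotic_onset_months_ago) &&
    x$psychotic_onset_months_ago <= 3
  bips <- any(bips_sub) && bips_onset && dur <= SIPS_BIPS_MAX_DURATION_DAYS &&
    !comorbid
  tr("bips", bips)

  # APS: severity 3-5, paired frequency >= 2, recency (onset within the past
  # year OR one-point escalation) plus presence over the past month
  aps_sub <- att & frq >= 2 & !sub
  recency <- (!is.na(x$onset_months_ago) && x$onset_months_ago <= 12) ||
    flag(x$severity_increased_past_year)
  present <- flag(x$present_past_month)
  tr("aps_recency", recency)
  tr("aps_present_past_month", present)
  aps <- any(aps_sub) && recency && present && !comorbid
  tr("aps", aps)

  fn <- functioning_criterion_sips_grd(x$gaf_current_month, x$gaf_12_months_ago)
  tr("functioning_gaf_drop", fn)
  grd <- (flag(x$schizotypal_pd) || flag(x$family_history_psychosis)) && fn
  tr("grd", grd)

  subgroups <- uhr_subgroup_levels[c(grd, aps, bips)]
  outcome <- if (length(subgroups)) "UHR+" else "UHR-"
  result_row("SIPS", outcome, subgroups, trace, notes)
}

#' Classify a cohort under the SIPS 5.0 criteria
#'
#' Applies the SIPS 5.0 diagnostic algorithm to each subject. Precedence:
#' (1) Psychosis (POPS) - a previous psychotic episode, or severity 6 with
#' paired frequency 3, or severity 6 with the urgency criterion (seriously
#' disorganizing and dangerous symptoms rule in psychosis no matter what the
#' duration); (2) BIPS - severity 6 with paired frequency of at least 1,
#' psychotic onset within 3 months and duration up to 3 months; (3) APS -
#' severity 3-5 with paired frequency of at least 2, begun within the past
#' year or one scale point higher than 12 months before, and present over the
#' past month; (4) GRD - schizotypal personality disorder or a first-degree
#' relative with psychosis, plus a 30% GAF drop over the last month compared
#' with 12 months before. Neither APS nor BIPS carries a functioning
#' requirement. A subscale whose symptoms are strongly intertwined with
#' substance use cannot qualify for APS/BIPS (other subscales still can),
#' and symptoms better accounted for by another disorder exclude APS/BIPS
#' but not POPS or GRD. The subgroup label `BLIPS` denotes the SIPS BIPS
#' syndrome so that outcomes align across instruments.
#'
#' @inheritParams classify_caarms
#' @return A tibble in the same layout as [classify_caarms()].
#' @export
#' @examples
#' x <- blank_cohort("s1",
#'   sips_p4_severity = 5, sips_p4_frequency = 2,
#'   onset_months_ago = 4, present_past_month = TRUE)
#' classify_sips(x)
classify_sips <- function(cohort) {
  cohort <- as_tibble(cohort)
  if (!all(has_sips(cohort))) {
    stop("instrument not rated: SIPS severities missing for subject(s) ",
         paste(head(cohort$subject_id[!has_sips(cohort)]), collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    classify_sips_one(as.list(cohort[i, ]))
  })
  assemble_results(cohort, rows)
}

#' Five-category outcome labels from a classification
#'
#' Collapses a classification tibble (from [classify_caarms()],
#' [classify_sips()] or a conversion) to outcome labels: 3 categories
#' (`UHR-`, `UHR+`, `Psychosis`) or 5 (UHR+ split into its primary subgroup
#' `GRD`, `APS`, `BLIPS`).
#'
#' @param result A classification tibble with `outcome` and `subgroup`.
#' @param categories 3 or 5.
#' @return An ordered factor of outcome labels.
#' @export
outcome_labels <- function(result, categories = 3) {
  categories <- match.arg(as.character(categories), c("3", "5"))
  if (categories == "3") return(outcome_factor(as.character(result$outcome)))
  lab <- as.character(result$outcome)
  pos <- lab == "UHR+"
  lab[pos] <- result$subgroup[pos]
  outcome5_factor(lab)
}
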
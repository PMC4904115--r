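# Naive, independently coded truth-table oracles for the two rule engines,
# written straight off the printed criterion tables as flat condition
# checks (no shared code with the package implementation), plus small
# builders for subject records.

# course/functioning configurations as plain lists
make_record <- function(id = "x", caarms_sev = rep(0, 4), caarms_frq = rep(0, 4),
                        sips_sev = rep(0, 5), sips_frq = rep(0, 5),
                        sips_sub = rep(FALSE, 5), ...) {
  args <- list(...)
  rec <- blank_cohort(id)
  for (i in 1:4) {
    rec[[paste0("caarms_p", i, "_severity")]] <- caarms_sev[i]
    rec[[paste0("caarms_p", i, "_frequency")]] <- caarms_frq[i]
  }
  for (i in 1:5) {
    rec[[paste0("sips_p", i, "_severity")]] <- sips_sev[i]
    rec[[paste0("sips_p", i, "_frequency")]] <- sips_frq[i]
    rec[[paste0("sips_p", i, "_substance_intertwined")]] <- sips_sub[i]
  }
  for (nm in names(args)) rec[[nm]] <- args[[nm]]
  rec
}

# default auxiliary data: recent onset, present, resolved brief course,
# functioning criterion met on both scales
aux_default <- list(
  onset_months_ago = 3, symptoms_gt_5y = FALSE,
  severity_increased_past_year = FALSE, present_past_month = TRUE,
  psychotic_duration_days = 2, psychotic_onset_months_ago = 1,
  resolved_without_antipsychotics = TRUE, danger_or_disorganization = FALSE,
  substance_peak_only = FALSE, comorbid_better_explains = FALSE,
  prior_psychotic_episode = FALSE,
  sofas_current = 49, sofas_premorbid = 80,
  sofas_drop_sustained_1m_12m = TRUE, sofas_below_50_12m = FALSE,
  gaf_current_month = 49, gaf_12_months_ago = 80,
  schizotypal_pd = FALSE, family_history_psychosis = FALSE)

record_with_aux <- function(aux, ...) {
  do.call(make_record, c(list(...), aux))
}

# --- naive CAARMS truth table -------------------------------------------
# aux is a plain list of course/functioning/trait fields
oracle_caarms <- function(sev, frq, aux) {
  psychotic <- c(sev[1] == 6, sev[2] == 6, sev[3] %in% c(5, 6), sev[4] == 6)
  attenuated <- c(sev[1] %in% 3:5, sev[2] %in% 3:5, sev[3] %in% 3:4,
                  sev[4] %in% 4:5)
  fn <- (!is.na(aux$sofas_premorbid) && aux$sofas_premorbid > 0 &&
           aux$sofas_current <= 0.7 * aux$sofas_premorbid &&
           isTRUE(aux$sofas_drop_sustained_1m_12m)) ||
    isTRUE(aux$sofas_below_50_12m)
  onset <- aux$onset_months_ago <= 12 && !isTRUE(aux$symptoms_gt_5y)
  nosub <- !isTRUE(aux$substance_peak_only)

  paired46 <- any(psychotic & frq %in% 4:6)
  if (isTRUE(aux$prior_psychotic_episode)) return("Psychosis")
  if (paired46 && (aux$psychotic_duration_days > 7 ||
                   !isTRUE(aux$resolved_without_antipsychotics))) {
    return("Psychosis")
  }
  blips <- paired46 && aux$psychotic_duration_days <= 7 &&
    isTRUE(aux$resolved_without_antipsychotics) && onset && fn && nosub
  aps <- (any(attenuated & frq %in% 3:6) || any(psychotic & frq == 3)) &&
    onset && fn && nosub
  grd <- (isTRUE(aux$schizotypal_pd) || isTRUE(aux$family_history_psychosis)) && fn
  if (blips || aps || grd) "UHR+" else "UHR-"
}

# --- naive SIPS truth table ---------------------------------------------
oracle_sips <- function(sev, frq, aux, sub = rep(FALSE, 5)) {
  psychotic <- sev == 6
  attenuated <- sev >= 3 & sev <= 5
  if (isTRUE(aux$prior_psychotic_episode)) return("Psychosis")
  if (any(psychotic & frq == 3)) return("Psychosis")
  if (any(psychotic) && isTRUE(aux$danger_or_disorganization)) return("Psychosis")
  bips <- any(psychotic & frq >= 1 & !sub) &&
    aux$psychotic_onset_months_ago <= 3 &&
    aux$psychotic_duration_days <= 91 &&
    !isTRUE(aux$comorbid_better_explains)
  aps <- any(attenuated & frq >= 2 & !sub) &&
    (aux$onset_months_ago <= 12 || isTRUE(aux$severity_increased_past_year)) &&
    isTRUE(aux$present_past_month) &&
    !isTRUE(aux$comorbid_better_explains)
  grd <- (isTRUE(aux$schizotypal_pd) || isTRUE(aux$family_history_psychosis)) &&
    !is.na(aux$gaf_12_months_ago) && aux$gaf_12_months_ago > 0 &&
    aux$gaf_current_month <= 0.7 * aux$gaf_12_months_ago
  if (bips || aps || grd) "UHR+" else "UHR-"
}

# a small set of course/functioning configurations exercising the gates
aux_configs <- list(
  default = aux_default,
  no_functioning = modifyList(aux_default, list(
    sofas_current = 70, sofas_drop_sustained_1m_12m = FALSE,
    sofas_below_50_12m = FALSE, gaf_current_month = 70)),
  long_duration = modifyList(aux_default, list(
    psychotic_duration_days = 30, psychotic_onset_months_ago = 2)),
  unresolved = modifyList(aux_default, list(
    resolved_without_antipsychotics = FALSE)),
  old_onset = modifyList(aux_default, list(
    onset_months_ago = 20, present_past_month = FALSE)),
  comorbid = modifyList(aux_default, list(comorbid_better_explains = TRUE)),
  danger = modifyList(aux_default, list(danger_or_disorganization = TRUE))
)

table3_counts <- function() {
  matrix(c(51, 0, 0, 5, 92, 14, 1, 9, 40), 3, byrow = TRUE,
         dimnames = list(c("UHR-", "UHR+", "Psychosis"),
                         c("UHR-", "UHR+", "Psychosis")))
}
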
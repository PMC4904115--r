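# Synthetic dual-instrument cohort generator. Each subject is assigned a
# latent clinical state; CAARMS ratings are drawn within the state's
# criterion bands and the SIPS ratings are derived through the domain and
# frequency crosswalks, so that with every discordance mechanism switched
# off both rule engines recover the state's canonical outcome. The
# documented discordance mechanisms are then injected at controlled
# prevalences: urgency flags on brief episodes, brief-episode durations in
# the 7 day-3 month window, the CAARMS P3 severity-5 band shift (psychotic
# under the CAARMS, attenuated once crosswalked to SIPS P4), comorbidity
# exclusion flags, and failures of the CAARMS SOFAS functioning criterion.

latent_states <- c("none", "trait_risk", "attenuated", "brief_psychotic",
                   "frank_psychotic")
latent_canonical <- c(none = "UHR-", trait_risk = "UHR+", attenuated = "UHR+",
                      brief_psychotic = "UHR+", frank_psychotic = "Psychosis")
latent_subgroup <- c(none = NA, trait_risk = "GRD", attenuated = "APS",
                     brief_psychotic = "BLIPS", frank_psychotic = NA)

#' Specification for a synthetic dual-instrument cohort
#'
#' Defaults emulate the composition of a help-seeking high-risk service
#' sample: the latent mixture matches the observed outcome marginals
#' (about 24% not at risk, 52% UHR+ of whom roughly a fifth have brief
#' psychotic episodes, 24% frank psychosis), and the mechanism prevalences
#' follow the documented discordance counts - 14 of 25 brief-episode
#' subjects with seriously disorganizing/dangerous symptoms (`p_danger =
#' 0.56`), 4 of 25 with durations between 7 days and 3 months
#' (`p_long_duration = 0.16`), about 8% of psychotic-intensity cases with
#' the perceptual band-shift severity (`p_band_shift = 0.08`), about 4.5%
#' of attenuated cases excluded by a better-explaining comorbid disorder
#' (`p_comorbid = 0.045`), and no functioning-criterion failures
#' (`p_functioning_fail = 0`, reflecting referral pathways pre-selected on
#' functional decline). `severity_concordance` is the probability that a
#' subscale's SIPS severity equals the crosswalked CAARMS severity; with
#' probability 1 minus it, the SIPS severity jitters by one point.
#'
#' @param n Number of subjects.
#' @param seed Integer seed; the same spec and seed give an identical cohort.
#' @param mixture Named probabilities over the latent states `none`,
#'   `trait_risk`, `attenuated`, `brief_psychotic`, `frank_psychotic`
#'   (must sum to 1).
#' @param p_danger Prevalence of the urgency flag among brief episodes.
#' @param p_long_duration Prevalence of 7 day-3 month durations among brief
#'   episodes without the urgency flag.
#' @param p_band_shift Prevalence of the CAARMS P3 severity-5 presentation
#'   among psychotic-intensity cases.
#' @param p_comorbid Prevalence of the comorbidity exclusion among
#'   attenuated cases.
#' @param p_functioning_fail Prevalence of CAARMS SOFAS-criterion failure
#'   among attenuated cases.
#' @param severity_concordance Cross-instrument severity concordance
#'   probability per subscale.
#' @return A list of class `cohort_spec`.
#' @export
#' @examples
#' cohort_spec(n = 50, seed = 7, p_danger = 0)
cohort_spec <- function(n = 212, seed = 1,
                        mixture = c(none = 0.241, trait_risk = 0.04,
                                    attenuated = 0.365, brief_psychotic = 0.118,
                                    frank_psychotic = 0.236),
                        p_danger = 0.56, p_long_duration = 0.16,
                        p_band_shift = 0.08, p_comorbid = 0.045,
                        p_functioning_fail = 0,
                        severity_concordance = 1) {
  if (n < 0 || n != round(n)) stop("n must be a nonnegative integer")
  if (!setequal(names(mixture), latent_states)) {
    stop("mixture must name the states: ", paste(latent_states, collapse = ", "))
  }
  mixture <- mixture[latent_states]
  if (abs(sum(mixture) - 1) > 1e-8) stop("mixture must sum to 1")
  probs <- c(p_danger = p_danger, p_long_duration = p_long_duration,
             p_band_shift = p_band_shift, p_comorbid = p_comorbid,
             p_functioning_fail = p_functioning_fail,
             severity_concordance = severity_concordance)
  if (any(probs < 0 | probs > 1) || any(mixture < 0)) {
    stop("probabilities must lie in [0,1]")
  }
  structure(list(n = as.integer(n), seed = as.integer(seed), mixture = mixture,
                 p_danger = p_danger, p_long_duration = p_long_duration,
                 p_band_shift = p_band_shift, p_comorbid = p_comorbid,
                 p_functioning_fail = p_functioning_fail,
                 severity_concordance = severity_concordance),
            class = "cohort_spec")
}

#' A cohort specification with every discordance mechanism switched off
#'
#' Convenience wrapper around [cohort_spec()] with all mechanism
#' prevalences zero and full cross-instrument severity concordance: both
#' rule engines then recover the latent outcome for every subject.
#'
#' @inheritParams cohort_spec
#' @param ... Passed to [cohort_spec()].
#' @return A `cohort_spec`.
#' @export
concordant_cohort_spec <- function(n = 212, seed = 1, ...) {
  cohort_spec(n = n, seed = seed, p_danger = 0, p_long_duration = 0,
              p_band_shift = 0, p_comorbid = 0, p_functioning_fail = 0,
              severity_concordance = 1, ...)
}

r_int <- function(n, lo, hi) lo + floor(runif(n) * (hi - lo + 1))

generate_subject <- function(id, state, spec) {
  rec <- as.list(blank_cohort(sprintf("S%04d", id))[1, ])
  rec$latent_state <- state

  # shared background: no prior episode, no exclusions unless injected
  rec$prior_psychotic_episode <- FALSE
  rec$substance_peak_only <- FALSE
  rec$comorbid_better_explains <- FALSE
  rec$danger_or_disorganization <- FALSE
  rec$symptoms_gt_5y <- FALSE
  rec$severity_increased_past_year <- runif(1) < 0.3
  rec$schizotypal_pd <- FALSE
  rec$family_history_psychosis <- FALSE
  for (i in 1:4) rec[[paste0("caarms_p", i, "_substance")]] <- 0
  for (i in 1:4) rec[[paste0("caarms_p", i, "_distress")]] <- r_int(1, 0, 100)

  # functioning: deteriorated for risk states, preserved otherwise
  deteriorated <- state %in% c("trait_risk", "attenuated", "brief_psychotic",
                               "frank_psychotic")
  if (deteriorated) {
    pre <- r_int(1, 70, 90)
    cur <- r_int(1, 30, floor(0.70 * pre))
    rec$sofas_premorbid <- pre
    rec$sofas_current <- cur
    rec$sofas_drop_sustained_1m_12m <- TRUE
    rec$sofas_below_50_12m <- cur < 50 && runif(1) < 0.5
    rec$gaf_12_months_ago <- pre
    rec$gaf_current_month <- cur
  } else {
    pre <- r_int(1, 60, 90)
    rec$sofas_premorbid <- pre
    rec$sofas_current <- r_int(1, max(50, floor(0.75 * pre)), pre)
    rec$sofas_drop_sustained_1m_12m <- FALSE
    rec$sofas_below_50_12m <- FALSE
    rec$gaf_12_months_ago <- pre
    rec$gaf_current_month <- rec$sofas_current
  }

  # baseline low-grade symptoms on all subscales
  sev <- r_int(4, 0, 2)
  frq <- r_int(4, 0, 3)
  rec$onset_months_ago <- r_int(1, 1, 11)
  rec$present_past_month <- TRUE
  rec$psychotic_duration_days <- 0
  rec$psychotic_onset_months_ago <- 0
  rec$resolved_without_antipsychotics <- TRUE

  idx <- r_int(1, 1, 4)  # index symptom domain
  band_shift <- FALSE
  if (state == "attenuated") {
    # attenuated band on the index subscale with qualifying frequency
    lo <- c(3, 3, 3, 4)[idx]
    hi <- c(5, 5, 4, 5)[idx]
    sev[idx] <- r_int(1, lo, hi)
    frq[idx] <- r_int(1, 3, 6)
    if (runif(1) < spec$p_comorbid) rec$comorbid_better_explains <- TRUE
    if (runif(1) < spec$p_functioning_fail) {
      rec$sofas_current <- r_int(1, ceiling(0.75 * rec$sofas_premorbid), 100)
      rec$sofas_drop_sustained_1m_12m <- FALSE
      rec$sofas_below_50_12m <- FALSE
    }
  } else if (state %in% c("brief_psychotic", "frank_psychotic")) {
    band_shift <- runif(1) < spec$p_band_shift
    if (band_shift) {
      idx <- 3          # perceptual domain, CAARMS psychotic band floor
      sev[idx] <- 5
    } else {
      sev[idx] <- 6
    }
    if (state == "brief_psychotic") {
      # short frank episode, resolving spontaneously; frequency 4 keeps the
      # crosswalked SIPS frequency below the sustained POPS band
      frq[idx] <- 4
      rec$psychotic_onset_months_ago <- r_int(1, 0, 2)
      rec$psychotic_duration_days <- r_int(1, 1, 7)
      rec$resolved_without_antipsychotics <- TRUE
      rec$onset_months_ago <- max(rec$psychotic_onset_months_ago, 1)
      if (runif(1) < spec$p_danger) {
        rec$danger_or_disorganization <- TRUE
      } else if (runif(1) < spec$p_long_duration) {
        rec$psychotic_duration_days <- r_int(1, 8, 85)
        rec$psychotic_onset_months_ago <-
          max(3, ceiling(rec$psychotic_duration_days / DAYS_PER_MONTH))
        rec$psychotic_onset_months_ago <- min(rec$psychotic_onset_months_ago, 3)
      }
    } else {
      frq[idx] <- r_int(1, 5, 6)   # sustained: crosswalks to SIPS frequency 3
      rec$psychotic_onset_months_ago <- r_int(1, 2, 6)
      rec$psychotic_duration_days <-
        r_int(1, 15, rec$psychotic_onset_months_ago * 30)
      rec$resolved_without_antipsychotics <- FALSE
      rec$onset_months_ago <- rec$psychotic_onset_months_ago
    }
  } else if (state == "trait_risk") {
    if (runif(1) < 0.5) rec$schizotypal_pd <- TRUE else rec$family_history_psychosis <- TRUE
  }

  for (i in 1:4) {
    rec[[paste0("caarms_p", i, "_severity")]] <- sev[i]
    rec[[paste0("caarms_p", i, "_frequency")]] <- frq[i]
  }

  # SIPS ratings derived through the crosswalk (P3 Grandiose Ideas unrated)
  tgt <- c(1, 2, 4, 5)
  for (i in 1:4) {
    s <- sev[i]
    if (runif(1) >= spec$severity_concordance) {
      s <- min(6, max(0, s + sample(c(-1, 1), 1)))
    }
    rec[[paste0("sips_p", tgt[i], "_severity")]] <- s
    rec[[paste0("sips_p", tgt[i], "_frequency")]] <-
      crosswalk_frequency(frq[i], "caarms2sips")
    rec[[paste0("sips_p", tgt[i], "_substance_intertwined")]] <- FALSE
  }
  rec$sips_p3_severity <- 0
  rec$sips_p3_frequency <- 0
  rec$sips_p3_substance_intertwined <- FALSE
  rec
}

#' Generate a synthetic dual-instrument cohort
#'
#' Draws `spec$n` subjects under the mixture and mechanism prevalences of
#' the specification (see [cohort_spec()]). The returned tibble follows the
#' cohort schema plus a provenance column `latent_state`; use
#' [latent_truth()] to recover the generating outcomes for
#' parameter-recovery checks.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble in the cohort schema with `latent_state` appended.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 10, seed = 42))
#' dplyr::count(cohort, latent_state)
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop("spec must be a cohort_spec")
  if (spec$n == 0) {
    out <- blank_cohort()
    out$latent_state <- character()
    return(out)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  states <- sample(latent_states, spec$n, replace = TRUE, prob = spec$mixture)
  rows <- lapply(seq_len(spec$n), function(i) {
    # per-subject substream keyed on the global seed and subject counter, so
    # a subject's record does not depend on n
    set.seed((spec$seed * 1000003L + i) %% .Machine$integer.max)
    as_tibble(generate_subject(i, states[i], spec))
  })
  bind_rows(rows)
}

#' Latent generating outcomes of a synthetic cohort
#'
#' Maps each subject's latent state to its canonical diagnostic outcome
#' (none to UHR-, trait risk/attenuated/brief episodes to UHR+, frank
#' psychosis to Psychosis).
#'
#' @param cohort A cohort generated by [generate_cohort()] (must carry the
#'   `latent_state` column).
#' @return A tibble with `subject_id`, `latent_state`, `outcome` (ordered
#'   factor) and `subgroup`.
#' @export
latent_truth <- function(cohort) {
  if (!"latent_state" %in% names(cohort)) {
    stop("cohort does not carry latent_state (not from generate_cohort?)")
  }
  tibble(
    subject_id = as.character(cohort$subject_id),
    latent_state = cohort$latent_state,
    outcome = outcome_factor(unname(latent_canonical[cohort$latent_state])),
    subgroup = unname(latent_subgroup[cohort$latent_state]))
}
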
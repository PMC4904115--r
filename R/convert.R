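# Pragmatic case conversion between CAARMS 12/2006 and SIPS 5.0:
# crosswalk the subscale ratings and frequencies onto the target
# instrument's scales, carry the shared clinical facts, then apply the
# target instrument's rule engine.
#
# Subscale crosswalk (psychopathological domains):
#   CAARMS P1 Unusual Thought Content  <-> SIPS P1 Unusual Thought Content
#   CAARMS P2 Non-Bizarre Ideas        <-> SIPS P2 Suspiciousness / P3
#     Grandiose Ideas (SIPS->CAARMS takes the highest of P2/P3)
#   CAARMS P3 Perceptual Abnormalities <-> SIPS P4 Perceptual Abnormalities
#   CAARMS P4 Disorganized Speech      <-> SIPS P5 Disorganized Communication
# Severities crosswalk unchanged on the shared 0-6 anchors.

# frequency crosswalks, indexed by source score + 1
freq_caarms_to_sips_map <- c(0, 0, 1, 2, 2, 3, 3)  # CAARMS 0-6 -> SIPS 0-3
freq_sips_to_caarms_map <- c(1, 2, 3, 5)           # SIPS 0-3 -> CAARMS 0-6

#' Crosswalk a frequency score between the CAARMS and SIPS scales
#'
#' Fixed monotone maps between the CAARMS 0-6 and SIPS 0-3 frequency
#' anchors: CAARMS `{0,1,2,3,4,5,6} -> {0,0,1,2,2,3,3}` SIPS (e.g. CAARMS 5
#' "daily, more than an hour per occasion" satisfies SIPS 3 "at least 1 h/d
#' for at least 4 d/wk"), and SIPS `{0,1,2,3} -> {1,2,3,5}` CAARMS.
#' Ambiguous cells are resolved conservatively downward (under-calling
#' frequency rather than over-calling diagnosis).
#'
#' @param freq Integer frequency scores on the source scale.
#' @param direction `"caarms2sips"` or `"sips2caarms"`.
#' @return Integer frequency scores on the target scale (`NA` in, `NA` out).
#' @export
#' @examples
#' crosswalk_frequency(0:6, "caarms2sips")
#' crosswalk_frequency(0:3, "sips2caarms")
crosswalk_frequency <- function(freq, direction = c("caarms2sips", "sips2caarms")) {
  direction <- match.arg(direction)
  map <- if (direction == "caarms2sips") freq_caarms_to_sips_map else freq_sips_to_caarms_map
  hi <- length(map) - 1L
  if (any(!is.na(freq) & (freq < 0 | freq > hi))) {
    stop("frequency out of [0,", hi, "]")
  }
  map[freq + 1L]
}

#' Convert CAARMS-rated subjects to predicted SIPS outcomes
#'
#' For each subject rated on the CAARMS 12/2006, builds the crosswalked SIPS
#' 5.0 record (severities carried along the domain map, CAARMS P2 feeding
#' SIPS P2; frequencies via [crosswalk_frequency()]; per-subscale
#' substance-intertwined flags derived from CAARMS substance code 2 or the
#' subject-level peak-intoxication flag) and applies [classify_sips()] with
#' the shared course, trait and functioning facts. When GAF scores are
#' absent, the SIPS GRD functioning window is proxied by the SOFAS scores
#' and an assumption note is recorded.
#'
#' @param cohort A data frame in the cohort schema with CAARMS ratings.
#' @return A tibble: classification columns as in [classify_sips()] plus the
#'   crosswalked `sips_*` rating columns and `conversion_notes`.
#' @export
#' @examples
#' x <- blank_cohort("s1",
#'   caarms_p1_severity = 4, caarms_p1_frequency = 4,
#'   onset_months_ago = 6, present_past_month = TRUE,
#'   sofas_current = 50, sofas_premorbid = 80,
#'   sofas_drop_sustained_1m_12m = TRUE)
#' caarms_to_sips(x)
caarms_to_sips <- function(cohort) {
  cohort <- as_tibble(cohort)
  if (!all(has_caarms(cohort))) {
    stop("instrument not rated: CAARMS severities missing for subject(s) ",
         paste(head(cohort$subject_id[!has_caarms(cohort)]), collapse = ", "))
  }
  xw <- cohort
  notes <- rep("", nrow(cohort))
  add_note <- function(idx, note) {
    notes[idx] <<- ifelse(nzchar(notes[idx]), paste(notes[idx], note, sep = "; "), note)
  }

  # domain map: CAARMS P1,P2,P3,P4 -> SIPS P1,P2,P4,P5; SIPS P3 unrated (0)
  tgt <- c(1, 2, 4, 5)
  for (j in 1:4) {
    xw[[paste0("sips_p", tgt[j], "_severity")]] <- cohort[[paste0("caarms_p", j, "_severity")]]
    xw[[paste0("sips_p", tgt[j], "_frequency")]] <-
      crosswalk_frequency(cohort[[paste0("caarms_p", j, "_frequency")]], "caarms2sips")
    code <- cohort[[paste0("caarms_p", j, "_substance")]]
    xw[[paste0("sips_p", tgt[j], "_substance_intertwined")]] <-
      (!is.na(code) & code == 2) | flag(cohort$substance_peak_only)
  }
  xw$sips_p3_severity <- 0
  xw$sips_p3_frequency <- 0
  xw$sips_p3_substance_intertwined <- FALSE
  add_note(rep(TRUE, nrow(cohort)),
           "SIPS P3 (Grandiose Ideas) not separately rated by the CAARMS; set to 0")

  gaf_missing <- is.na(cohort$gaf_current_month) | is.na(cohort$gaf_12_months_ago)
  if (any(gaf_missing)) {
    xw$gaf_current_month[gaf_missing] <- cohort$sofas_current[gaf_missing]
    xw$gaf_12_months_ago[gaf_missing] <- cohort$sofas_premorbid[gaf_missing]
    add_note(gaf_missing, "GAF drop proxied by SOFAS scores")
  }

  res <- classify_sips(xw)
  bind_cols(res, xw[sips_rating_cols], tibble(conversion_notes = notes))
}

#' Convert SIPS-rated subjects to predicted CAARMS outcomes
#'
#' For each subject rated on the SIPS 5.0, builds the crosswalked CAARMS
#' 12/2006 record: severities carried along the domain map with CAARMS P2
#' receiving the highest of SIPS P2/P3 (and that subscale's frequency);
#' frequencies via [crosswalk_frequency()], with a qualifying-frequency
#' floor - a SIPS subscale at severity 6 whose frequency already qualifies
#' under the SIPS (frequency of at least 1) represents established
#' psychotic-intensity symptomatology, so its crosswalked CAARMS frequency
#' is raised to at least 4, the corresponding CAARMS qualifying band (an
#' assumption note is recorded). [classify_caarms()] is then applied with
#' the shared clinical facts, so SIPS cases lacking the CAARMS SOFAS
#' deterioration criterion convert to UHR-, psychotic-intensity episodes
#' lasting over 7 days convert to Psychosis, and urgency-driven SIPS
#' psychoses of up to 7 days with spontaneous resolution convert to BLIPS.
#'
#' @param cohort A data frame in the cohort schema with SIPS ratings.
#' @return A tibble: classification columns as in [classify_caarms()] plus
#'   the crosswalked `caarms_*` rating columns and `conversion_notes`.
#' @export
sips_to_caarms <- function(cohort) {
  cohort <- as_tibble(cohort)
  if (!all(has_sips(cohort))) {
    stop("instrument not rated: SIPS severities missing for subject(s) ",
         paste(head(cohort$subject_id[!has_sips(cohort)]), collapse = ", "))
  }
  xw <- cohort
  notes <- rep("", nrow(cohort))
  add_note <- function(idx, note) {
    notes[idx] <<- ifelse(nzchar(notes[idx]), paste(notes[idx], note, sep = "; "), note)
  }

  sev <- as.matrix(cohort[paste0("sips_p", 1:5, "_severity")])
  frq <- as.matrix(cohort[paste0("sips_p", 1:5, "_frequency")])
  sub <- as.matrix(cohort[paste0("sips_p", 1:5, "_substance_intertwined")])
  sev0 <- ifelse(is.na(sev), 0, sev)
  frq0 <- ifelse(is.na(frq), 0, frq)

  # CAARMS P2 takes the highest of SIPS P2/P3 (ties: P2), with its frequency
  use_p3 <- sev0[, 3] > sev0[, 2]
  p2_sev <- ifelse(is.na(sev[, 2]) & is.na(sev[, 3]), NA,
                   pmax(sev0[, 2], sev0[, 3]))
  p2_frq <- ifelse(use_p3, frq[, 3], frq[, 2])
  p2_sub <- ifelse(use_p3, sub[, 3], sub[, 2])
  if (any(use_p3)) add_note(use_p3, "CAARMS P2 taken from SIPS P3 (higher of P2/P3)")

  src_sev <- cbind(sev[, 1], p2_sev, sev[, 4], sev[, 5])
  src_frq <- cbind(frq[, 1], p2_frq, frq[, 4], frq[, 5])
  src_sub <- cbind(sub[, 1], p2_sub, sub[, 4], sub[, 5])

  floored <- rep(FALSE, nrow(cohort))
  for (j in 1:4) {
    s <- src_sev[, j]
    f <- src_frq[, j]
    mapped <- crosswalk_frequency(f, "sips2caarms")
    floor_j <- !is.na(s) & s == 6 & !is.na(f) & f >= 1 & mapped < 4
    mapped[floor_j] <- 4
    floored <- floored | floor_j
    xw[[paste0("caarms_p", j, "_severity")]] <- s
    xw[[paste0("caarms_p", j, "_frequency")]] <- mapped
    xw[[paste0("caarms_p", j, "_substance")]] <-
      ifelse(!is.na(src_sub[, j]) & src_sub[, j], 2, 0)
    xw[[paste0("caarms_p", j, "_distress")]] <- NA_real_
  }
  if (any(floored)) {
    add_note(floored,
             "SIPS-qualifying psychotic frequency raised to CAARMS band 4-6")
  }

  res <- classify_caarms(xw)
  bind_cols(res, xw[caarms_rating_cols], tibble(conversion_notes = notes))
}

#' Convert a cohort and pair predictions with observed target outcomes
#'
#' Runs the conversion engine over a cohort in the given direction and, for
#' subjects also rated on the target instrument, classifies them directly to
#' provide an observed outcome for validation. Per-record conversion
#' failures are collected into the `error` column rather than aborting the
#' run.
#'
#' @param cohort A data frame in the cohort schema.
#' @param direction `"caarms2sips"` or `"sips2caarms"`.
#' @return A tibble with one row per subject: `subject_id`, `observed` and
#'   `predicted` outcomes (ordered factors, `NA` observed when the target
#'   instrument was not rated), `observed_subgroup`, `predicted_subgroup`,
#'   `conversion_notes` and `error`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 20, seed = 1))
#' convert_cohort(cohort, "caarms2sips")
convert_cohort <- function(cohort, direction = c("caarms2sips", "sips2caarms")) {
  direction <- match.arg(direction)
  cohort <- as_tibble(cohort)
  empty <- tibble(
    subject_id = character(), observed = outcome_factor(character()),
    predicted = outcome_factor(character()),
    observed_subgroup = character(), predicted_subgroup = character(),
    conversion_notes = character(), error = character())
  if (nrow(cohort) == 0) return(empty)

  convert_fun <- if (direction == "caarms2sips") caarms_to_sips else sips_to_caarms
  classify_target <- if (direction == "caarms2sips") classify_sips else classify_caarms
  target_rated <- if (direction == "caarms2sips") has_sips(cohort) else has_caarms(cohort)

  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    rec <- cohort[i, ]
    out <- tibble(
      subject_id = as.character(rec$subject_id),
      observed = outcome_factor(NA_character_),
      predicted = outcome_factor(NA_character_),
      observed_subgroup = NA_character_, predicted_subgroup = NA_character_,
      conversion_notes = NA_character_, error = NA_character_)
    pred <- tryCatch(convert_fun(rec), error = function(e) conditionMessage(e))
    if (is.character(pred)) {
      out$error <- pred
      return(out)
    }
    out$predicted <- outcome_factor(as.character(pred$outcome))
    out$predicted_subgroup <- pred$subgroup
    out$conversion_notes <- pred$conversion_notes
    if (target_rated[i]) {
      obs <- classify_target(rec)
      out$observed <- outcome_factor(as.character(obs$outcome))
      out$observed_subgroup <- obs$subgroup
    }
    out
  })
  bind_rows(rows)
}
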
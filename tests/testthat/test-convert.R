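test_that("frequency crosswalks are total, monotone and match the anchor map", {
  expect_identical(crosswalk_frequency(0:6, "caarms2sips"), c(0, 0, 1, 2, 2, 3, 3))
  expect_identical(crosswalk_frequency(0:3, "sips2caarms"), c(1, 2, 3, 5))
  expect_true(all(diff(crosswalk_frequency(0:6, "caarms2sips")) >= 0))
  expect_true(all(diff(crosswalk_frequency(0:3, "sips2caarms")) >= 0))
  expect_error(crosswalk_frequency(7, "caarms2sips"), "out of")
  expect_error(crosswalk_frequency(4, "sips2caarms"), "out of")
})

test_that("severity crosswalk is monotone in the source severity", {
  # raising a CAARMS severity never lowers the mapped SIPS severity
  for (sub in 1:4) {
    prev <- -1
    for (s in 0:6) {
      sev <- rep(0, 4); sev[sub] <- s
      rec <- record_with_aux(aux_default, caarms_sev = sev, caarms_frq = rep(2, 4))
      xw <- caarms_to_sips(rec)
      mapped <- max(unlist(xw[paste0("sips_p", 1:5, "_severity")]))
      expect_gte(mapped, prev)
      prev <- mapped
    }
  }
})

test_that("discordance mechanism: CAARMS BLIPS with urgency becomes SIPS Psychosis", {
  rec <- record_with_aux(aux_default, caarms_sev = c(6, 0, 0, 0),
                         caarms_frq = c(4, 0, 0, 0),
                         psychotic_duration_days = 3,
                         danger_or_disorganization = TRUE)
  expect_identical(classify_caarms(rec)$subgroup, "BLIPS")
  expect_identical(as.character(caarms_to_sips(rec)$outcome), "Psychosis")
})

test_that("discordance mechanism: sub-POPS CAARMS Psychosis becomes SIPS BIPS", {
  # psychotic intensity, frequency 4 (below the sustained POPS band), 20 days
  rec <- record_with_aux(aux_default, caarms_sev = c(6, 0, 0, 0),
                         caarms_frq = c(4, 0, 0, 0),
                         psychotic_duration_days = 20,
                         psychotic_onset_months_ago = 1)
  expect_identical(as.character(classify_caarms(rec)$outcome), "Psychosis")
  res <- caarms_to_sips(rec)
  expect_identical(as.character(res$outcome), "UHR+")
  expect_identical(res$subgroup, "BLIPS")
})

test_that("discordance mechanism: CAARMS P3 severity 5 is attenuated under SIPS", {
  rec <- record_with_aux(aux_default, caarms_sev = c(0, 0, 5, 0),
                         caarms_frq = c(0, 0, 5, 0),
                         psychotic_duration_days = 20,
                         psychotic_onset_months_ago = 1)
  expect_identical(as.character(classify_caarms(rec)$outcome), "Psychosis")
  res <- caarms_to_sips(rec)
  expect_identical(res$sips_p4_severity, 5)
  expect_identical(as.character(res$outcome), "UHR+")
  expect_identical(res$subgroup, "APS")
  # and the reverse shift: SIPS P4 severity 6 stays psychotic as CAARMS P3
  rev <- record_with_aux(aux_default, sips_sev = c(0, 0, 0, 6, 0),
                         sips_frq = c(0, 0, 0, 1, 0),
                         psychotic_duration_days = 30,
                         psychotic_onset_months_ago = 1)
  out <- sips_to_caarms(rev)
  expect_identical(out$caarms_p3_severity, 6)
  expect_identical(as.character(out$outcome), "Psychosis")
})

test_that("discordance mechanism: comorbidity unmakes the SIPS diagnosis only", {
  rec <- record_with_aux(aux_configs$comorbid, caarms_sev = c(4, 0, 0, 0),
                         caarms_frq = c(4, 0, 0, 0))
  expect_identical(classify_caarms(rec)$subgroup, "APS")
  expect_identical(as.character(caarms_to_sips(rec)$outcome), "UHR-")
})

test_that("discordance mechanism: the CAARMS functioning gate unmakes SIPS APS/BIPS", {
  rec <- record_with_aux(aux_configs$no_functioning,
                         sips_sev = c(4, 0, 0, 0, 0), sips_frq = c(2, 0, 0, 0, 0))
  expect_identical(classify_sips(rec)$subgroup, "APS")
  expect_identical(as.character(sips_to_caarms(rec)$outcome), "UHR-")
})

test_that("SIPS Psychosis by urgency alone converts back to CAARMS BLIPS", {
  rec <- record_with_aux(aux_configs$danger, sips_sev = c(6, 0, 0, 0, 0),
                         sips_frq = c(1, 0, 0, 0, 0),
                         psychotic_duration_days = 2,
                         psychotic_onset_months_ago = 0)
  expect_identical(as.character(classify_sips(rec)$outcome), "Psychosis")
  back <- sips_to_caarms(rec)
  expect_identical(as.character(back$outcome), "UHR+")
  expect_identical(back$subgroup, "BLIPS")
})

test_that("CAARMS Vulnerability converts to SIPS GRD via GAF, SOFAS as proxy", {
  rec <- record_with_aux(aux_default, family_history_psychosis = TRUE)
  expect_identical(classify_caarms(rec)$subgroup, "GRD")
  res <- caarms_to_sips(rec)
  expect_identical(res$subgroup, "GRD")
  # GAF present and preserved: no drop, no SIPS GRD
  nogaf <- modifyList(aux_default, list(gaf_current_month = 75, gaf_12_months_ago = 80))
  rec2 <- record_with_aux(nogaf, family_history_psychosis = TRUE)
  expect_identical(classify_caarms(rec2)$subgroup, "GRD")
  expect_identical(as.character(caarms_to_sips(rec2)$outcome), "UHR-")
  # GAF absent: SOFAS proxy, noted
  rec3 <- record_with_aux(modifyList(aux_default, list(
    gaf_current_month = NA_real_, gaf_12_months_ago = NA_real_)),
    family_history_psychosis = TRUE)
  res3 <- caarms_to_sips(rec3)
  expect_identical(res3$subgroup, "GRD")
  expect_match(res3$conversion_notes, "proxied by SOFAS")
})

test_that("conversion is deterministic and all-zero ratings convert to UHR-", {
  rec <- record_with_aux(aux_default)
  expect_identical(caarms_to_sips(rec)$outcome, caarms_to_sips(rec)$outcome)
  expect_identical(as.character(caarms_to_sips(rec)$outcome), "UHR-")
  expect_identical(as.character(sips_to_caarms(rec)$outcome), "UHR-")
})

test_that("round trip preserves the CAARMS outcome when no mechanism is active", {
  set.seed(53)
  cohort <- generate_cohort(concordant_cohort_spec(n = 120, seed = 9))
  direct <- classify_caarms(cohort)
  fwd <- caarms_to_sips(cohort)
  # rebuild a cohort from the crosswalked SIPS ratings plus shared facts
  mid <- cohort
  for (col in grep("^sips_", cohort_columns(), value = TRUE)) mid[[col]] <- fwd[[col]]
  back <- sips_to_caarms(mid)
  expect_identical(as.character(back$outcome), as.character(direct$outcome))
  expect_identical(back$subgroup, direct$subgroup)
})

test_that("convert_cohort pairs predictions with observed target outcomes", {
  expect_identical(nrow(convert_cohort(blank_cohort(), "caarms2sips")), 0L)

  cohort <- generate_cohort(concordant_cohort_spec(n = 60, seed = 2))
  for (d in c("caarms2sips", "sips2caarms")) {
    cv <- convert_cohort(cohort, d)
    expect_identical(nrow(cv), 60L)
    expect_identical(as.character(cv$predicted), as.character(cv$observed))
  }

  # a record without target ratings: prediction filled, observed unknown
  solo <- record_with_aux(aux_default, caarms_sev = c(4, 0, 0, 0),
                          caarms_frq = c(4, 0, 0, 0))
  for (col in grep("^sips_", cohort_columns(), value = TRUE)) solo[[col]] <- NA
  cv <- convert_cohort(solo, "caarms2sips")
  expect_false(is.na(cv$predicted))
  expect_true(is.na(cv$observed))

  # a record missing the source instrument yields a collected error, not a stop
  nosrc <- blank_cohort("z", sips_p1_severity = 3)
  cv2 <- convert_cohort(nosrc, "caarms2sips")
  expect_match(cv2$error, "instrument not rated")
  expect_true(is.na(cv2$predicted))
})

test_that("conversion accuracy exceeds 0.85 both ways at documented prevalences", {
  cohort <- generate_cohort(cohort_spec(n = 300, seed = 17))
  for (d in c("caarms2sips", "sips2caarms")) {
    cv <- convert_cohort(cohort, d)
    acc <- accuracy_metrics(cv$predicted, cv$observed)
    expect_gt(acc$roc_area, 0.85)
  }
})
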
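test_that("Cohen's kappa reproduces the published dual-instrument comparison", {
  k <- cohen_kappa(table3_counts())
  expect_equal(100 * k$po, 86.32, tolerance = 5e-3)
  expect_equal(100 * k$pe, 37.42, tolerance = 5e-3)
  expect_equal(k$kappa, 0.781, tolerance = 1e-3)
  expect_equal(k$z, 15.83, tolerance = 1e-3)
  expect_equal(k$conf_low, 0.684, tolerance = 1e-3)
  expect_equal(k$conf_high, 0.878, tolerance = 1e-3)
  expect_equal(k$pabak, 0.795, tolerance = 1e-3)
  expect_lt(k$p_value, 0.001)
})

test_that("kappa boundary behaviour: perfect agreement, independence, degeneracy", {
  expect_equal(cohen_kappa(matrix(c(10, 0, 0, 10), 2))$kappa, 1)
  expect_equal(cohen_kappa(matrix(25, 2, 2))$kappa, 0)
  expect_error(cohen_kappa(matrix(c(10, 0, 0, 0), 2)), "undefined")
  expect_error(cohen_kappa(matrix(0, 2, 2)), "empty")
  # kappa <= Po and kappa = 1 only for purely diagonal tables
  set.seed(61)
  for (i in 1:25) {
    tab <- matrix(rpois(9, 8), 3)
    k <- tryCatch(cohen_kappa(tab), error = function(e) NULL)
    if (is.null(k)) next
    expect_lte(k$kappa, k$po + 1e-12)
    if (k$kappa == 1) expect_true(all(tab[upper.tri(tab) | lower.tri(tab)] == 0))
  }
})

test_that("kappa agrees with an independent implementation and PABAK tracks Po", {
  skip_if_not_installed("e1071")
  set.seed(62)
  for (i in 1:10) {
    tab <- matrix(rpois(9, 10) + 1, 3)
    expect_equal(cohen_kappa(tab)$kappa, e1071::classAgreement(tab)$kappa,
                 tolerance = 1e-10)
  }
  # PABAK strictly increases with observed agreement at fixed N and k
  pab <- function(d) cohen_kappa(matrix(c(d, 30 - d, 10, 20), 2))$pabak
  expect_true(all(diff(sapply(1:29, pab)) > 0))
})

test_that("expected chance agreement matches a margin-permutation estimate", {
  set.seed(63)
  tab <- matrix(c(20, 4, 6, 3, 15, 2, 1, 5, 9), 3)
  k <- cohen_kappa(tab)
  a <- rep(rep(rownames(tab) <- colnames(tab) <- paste0("c", 1:3),
               1), times = rowSums(tab))
  b <- rep(colnames(tab), times = colSums(tab))
  sims <- replicate(4000, mean(a == sample(b)))
  expect_equal(k$pe, mean(sims), tolerance = 0.01)
})

test_that("weighted kappa: identity weights reduce to Cohen's kappa", {
  set.seed(64)
  for (i in 1:5) {
    tab <- matrix(rpois(9, 12) + 1, 3)
    kw <- weighted_kappa(tab, weights = diag(3))
    k <- cohen_kappa(tab)
    expect_equal(kw$kappa, k$kappa, tolerance = 1e-12)
    expect_equal(kw$po, k$po, tolerance = 1e-12)
    expect_equal(kw$se0, k$se0, tolerance = 1e-10)
  }
})

test_that("weighted kappa: degenerate and perfect cases", {
  expect_error(weighted_kappa(matrix(c(10, 2, 3, 10), 2),
                              weights = matrix(1, 2, 2)), "undefined")
  w <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(weighted_kappa(matrix(c(10, 0, 0, 10), 2), weights = w)$kappa, 1)
  # functional-level scores build linear absolute-difference weights
  kw <- weighted_kappa(table3_counts(), scores = c(1, 0.84, 0))
  expect_equal(kw$weights[1, 2], 1 - 0.16, tolerance = 1e-12)
  expect_equal(kw$weights[2, 3], 1 - 0.84, tolerance = 1e-12)
  expect_true(kw$kappa > 0 && kw$kappa < 1)
})

test_that("Bowker symmetry test matches the published value and base R", {
  b <- bowker_test(table3_counts())
  expect_equal(b$statistic, 7.087, tolerance = 1e-3)
  expect_equal(b$df, 3)
  expect_equal(b$p_value, 0.069, tolerance = 5e-3)

  m <- mcnemar.test(table3_counts(), correct = FALSE)
  expect_equal(b$statistic, unname(m$statistic), tolerance = 1e-10)
  expect_equal(b$p_value, m$p.value, tolerance = 1e-10)
})

test_that("Bowker: symmetry, transposition invariance, degenerate pairs", {
  sym <- matrix(c(5, 3, 2, 3, 8, 1, 2, 1, 9), 3)
  expect_equal(bowker_test(sym)$statistic, 0)
  expect_equal(bowker_test(matrix(c(0, 1, 5, 0), 2))$statistic, (5 - 1)^2 / 6,
               tolerance = 1e-12)
  set.seed(65)
  for (i in 1:10) {
    tab <- matrix(rpois(16, 5), 4)
    expect_equal(bowker_test(tab)$statistic, bowker_test(t(tab))$statistic)
  }
  # all-zero off-diagonal: statistic 0, df 0, p 1
  d <- diag(c(4, 5, 6))
  rownames(d) <- colnames(d) <- letters[1:3]
  b <- bowker_test(d)
  expect_identical(c(b$statistic, b$df, b$p_value), c(0, 0, 1))
  # exact binomial variant for 2x2
  tab2 <- matrix(c(10, 2, 7, 12), 2)
  expect_equal(bowker_test(tab2, exact = TRUE)$p_value,
               binom.test(tab2[1, 2], tab2[1, 2] + tab2[2, 1])$p.value)
})

test_that("adjusted residuals match the published table and base R", {
  r <- adjusted_residuals(table3_counts())
  expect_equal(round(r$residuals, 1),
               matrix(c(13.5, -7.8, -4.8, -7.7, 10.8, -4.5, -4.5, -4.8, 10.1),
                      3, byrow = TRUE,
                      dimnames = dimnames(table3_counts())))
  expect_equal(r$min_expected, 12.74, tolerance = 5e-3)
  expect_equal(unclass(r$residuals), unclass(chisq.test(table3_counts())$stdres),
               tolerance = 1e-10)
  # for 2x2 tables r11^2 equals the Pearson chi-square statistic
  tab2 <- matrix(c(30, 10, 12, 25), 2)
  r2 <- adjusted_residuals(tab2)
  expect_equal(r2$residuals[1, 1]^2,
               unname(chisq.test(tab2, correct = FALSE)$statistic),
               tolerance = 1e-10)
  # independence table: all residuals zero
  ind <- outer(c(10, 20), c(3, 7)) / 10
  expect_equal(max(abs(adjusted_residuals(ind)$residuals)), 0, tolerance = 1e-12)
  expect_error(adjusted_residuals(matrix(c(1, 2, 0, 0), 2)), "zero column marginal")
  expect_error(adjusted_residuals(matrix(c(1, 0, 2, 0), 2)), "zero row marginal")
})

test_that("outcome crosstab counts paired labels in both layouts", {
  a <- c("UHR+", "UHR+", "UHR-")
  b <- c("Psychosis", "Psychosis", "UHR-")
  tab <- outcome_crosstab(a, b)
  expect_equal(tab["UHR+", "Psychosis"], 2)
  expect_equal(tab["UHR-", "UHR-"], 1)
  expect_equal(sum(tab), 3)
  expect_error(outcome_crosstab(a, b[1:2]), "length")

  cohort <- generate_cohort(concordant_cohort_spec(n = 40, seed = 3))
  t5 <- outcome_crosstab(classify_caarms(cohort), classify_sips(cohort),
                         categories = 5)
  expect_identical(rownames(t5), c("UHR-", "GRD", "APS", "BLIPS", "Psychosis"))
  expect_equal(sum(t5), 40)
  expect_equal(sum(diag(t5)), 40)  # concordant cohort
})

test_that("accuracy metrics reproduce the validation-style 2x2 figures", {
  predicted <- rep(c("Psychosis", "other", "Psychosis", "other"),
                   c(26, 5, 2, 60))
  observed <- rep(c("Psychosis", "Psychosis", "other", "other"),
                  c(26, 5, 2, 60))
  acc <- accuracy_metrics(predicted, observed, positive_class = "Psychosis")
  expect_equal(100 * acc$sensitivity, 83.87, tolerance = 5e-3)
  expect_equal(100 * acc$specificity, 96.77, tolerance = 5e-3)
  expect_equal(acc$roc_area, 0.903, tolerance = 5e-4)

  perf <- accuracy_metrics(observed, observed)
  expect_equal(perf$sensitivity, 1)
  expect_equal(perf$roc_area, 1)

  none <- accuracy_metrics(rep("other", length(observed)), observed)
  expect_equal(none$sensitivity, 0)
  expect_equal(none$specificity, 1)
  expect_equal(none$roc_area, 0.5)
})

test_that("single-threshold ROC area equals rank-based concordance", {
  skip_if_not_installed("pROC")
  set.seed(66)
  for (i in 1:5) {
    obs <- sample(c("Psychosis", "other"), 80, TRUE)
    pred <- ifelse(runif(80) < 0.7, obs, sample(c("Psychosis", "other"), 80, TRUE))
    acc <- accuracy_metrics(pred, obs)
    auc <- suppressMessages(pROC::auc(
      response = factor(obs, c("other", "Psychosis")),
      predictor = as.numeric(pred == "Psychosis"), quiet = TRUE))
    expect_equal(acc$roc_area, as.numeric(auc), tolerance = 1e-10)
  }
})

test_that("tidy and glance methods expose the statistics tidily", {
  k <- cohen_kappa(table3_counts())
  td <- tidy(k)
  expect_identical(td$term, "kappa")
  expect_equal(td$estimate, k$kappa)
  gl <- glance(k)
  expect_equal(gl$pabak, k$pabak)
  expect_equal(nrow(tidy(bowker_test(table3_counts()))), 3L)
  rt <- tidy(adjusted_residuals(table3_counts()))
  expect_identical(nrow(rt), 9L)
  expect_true(rt$significant[rt$row == "UHR-" & rt$col == "UHR-"])
})
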
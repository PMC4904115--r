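# Paired-outcome agreement statistics for k x k contingency tables:
# percent agreement, Cohen's kappa with the fixed-marginal null standard
# error (z test and CI), weighted kappa, PABAK, the McNemar-Bowker symmetry
# test, and independence expected counts with adjusted residuals.

as_crosstab <- function(tab) {
  if (is.data.frame(tab)) tab <- as.matrix(tab)
  tab <- unclass(tab)
  if (!is.matrix(tab) || nrow(tab) != ncol(tab)) {
    stop("contingency table must be a square matrix")
  }
  if (nrow(tab) < 2) stop("contingency table must be at least 2 x 2")
  if (any(tab < 0) || any(is.na(tab))) stop("counts must be nonnegative and complete")
  if (is.null(rownames(tab))) {
    rownames(tab) <- colnames(tab) <- paste0("cat", seq_len(nrow(tab)))
  }
  if (!identical(rownames(tab), colnames(tab))) {
    stop("row and column labels must be identical")
  }
  storage.mode(tab) <- "double"
  tab
}

#' Cross-tabulate paired diagnostic outcomes
#'
#' Builds the k x k contingency table of paired outcomes from two
#' classification tibbles (or label vectors) paired by position. Supports
#' the 3-category layout (`UHR-`/`UHR+`/`Psychosis`) and the 5-category
#' layout in which UHR+ is split into its primary subgroup
#' (`GRD`/`APS`/`BLIPS`).
#'
#' @param a,b Classification tibbles (with `outcome`/`subgroup` columns) or
#'   factors/character vectors of labels; rows of `a` index the table rows.
#' @param categories 3 or 5 (ignored when plain label vectors are supplied).
#' @return A labelled square matrix of counts.
#' @export
#' @examples
#' outcome_crosstab(c("UHR+", "UHR-"), c("UHR+", "UHR-"))
outcome_crosstab <- function(a, b, categories = 3) {
  to_labels <- function(x) {
    if (is.data.frame(x)) outcome_labels(x, categories)
    else if (is.factor(x)) x
    else factor(x, levels = if (all(x %in% uhr_outcome_levels)) uhr_outcome_levels
                else sort(unique(c(a, b))))
  }
  la <- to_labels(a)
  lb <- to_labels(b)
  if (length(la) != length(lb)) stop("paired outcome lists differ in length")
  lev <- union(levels(la), levels(lb))
  tab <- table(factor(la, lev), factor(lb, lev))
  m <- matrix(as.numeric(tab), nrow(tab), dimnames = list(lev, lev))
  m
}

#' Cohen's kappa with null-standard-error inference and PABAK
#'
#' Observed agreement Po, expected chance agreement Pe from the marginals,
#' kappa `(Po - Pe) / (1 - Pe)`, the fixed-marginal null standard error
#' `SE0 = sqrt(Pe + Pe^2 - sum_i p_i. p_.i (p_i. + p_.i)) / ((1 - Pe) sqrt(N))`,
#' the z statistic `kappa / SE0` with its two-sided normal p value, a
#' confidence interval, and the prevalence- and bias-adjusted kappa
#' `PABAK = (k Po - 1) / (k - 1)`. By convention the confidence interval
#' uses the null standard error (`se = "null"`); the large-sample non-null
#' standard error is available with `se = "asymptotic"` (the z statistic
#' always uses SE0).
#'
#' @param tab A square contingency table (matrix or data frame) with
#'   identical row/column labels; rows are instrument A, columns instrument B.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @param se `"null"` (default) or `"asymptotic"`: which standard error the
#'   confidence interval uses.
#' @return An object of class `uhr_kappa`: a list with `po`, `pe`, `kappa`,
#'   `se0`, `se_asymptotic`, `z`, `p_value`, `conf_low`, `conf_high`,
#'   `pabak`, `n`, `k` and the table. Supports `print()`, `tidy()` and
#'   `glance()`.
#' @export
#' @examples
#' tab <- matrix(c(51, 0, 0, 5, 92, 14, 1, 9, 40), 3, byrow = TRUE,
#'               dimnames = list(c("UHR-", "UHR+", "Psychosis"),
#'                               c("UHR-", "UHR+", "Psychosis")))
#' cohen_kappa(tab)
cohen_kappa <- function(tab, conf_level = 0.95, se = c("null", "asymptotic")) {
  se <- match.arg(se)
  tab <- as_crosstab(tab)
  n <- sum(tab)
  if (n == 0) stop("empty contingency table")
  k <- nrow(tab)
  p <- tab / n
  pr <- rowSums(p)
  pc <- colSums(p)
  po <- sum(diag(p))
  pe <- sum(pr * pc)
  if (1 - pe <= .Machine$double.eps) stop("kappa undefined: chance agreement is 1")
  kappa <- (po - pe) / (1 - pe)
  se0 <- sqrt(max(0, pe + pe^2 - sum(pr * pc * (pr + pc)))) / ((1 - pe) * sqrt(n))

  # large-sample non-null SE (Fleiss, Cohen & Everitt)
  a <- sum(diag(p) * (1 - (pr + pc) * (1 - kappa))^2)
  off <- p * outer(pc, pr, "+")^2
  diag(off) <- 0
  b <- (1 - kappa)^2 * sum(off)
  cc <- (kappa - pe * (1 - kappa))^2
  se_asym <- sqrt(max(0, a + b - cc)) / ((1 - pe) * sqrt(n))

  z <- kappa / se0
  ci_se <- if (se == "null") se0 else se_asym
  zq <- qnorm(1 - (1 - conf_level) / 2)
  structure(list(
    po = po, pe = pe, kappa = kappa, se0 = se0, se_asymptotic = se_asym,
    z = z, p_value = 2 * pnorm(-abs(z)),
    conf_low = kappa - zq * ci_se, conf_high = kappa + zq * ci_se,
    conf_level = conf_level, se_used = se,
    pabak = (k * po - 1) / (k - 1), n = n, k = k, table = tab,
    weighted = FALSE), class = "uhr_kappa")
}

#' Weighted kappa for ordered or scored categories
#'
#' Kappa with partial credit for near-agreement: weighted observed agreement
#' `sum w_ij p_ij` and weighted chance agreement `sum w_ij p_i. p_.j`. The
#' weight matrix may be given directly, or built from per-category scores as
#' absolute-difference linear weights `w_ij = 1 - |s_i - s_j| / range(s)`
#' (e.g. scores reflecting the relative baseline functional level of the
#' outcome groups, such as UHR- = 1, UHR+ = 0.84, Psychosis = 0). Inference
#' uses the weighted fixed-marginal null standard error.
#'
#' @inheritParams cohen_kappa
#' @param weights Optional k x k symmetric weight matrix with unit diagonal.
#' @param scores Optional numeric vector of k category scores used to build
#'   linear absolute-difference weights when `weights` is not given.
#' @return An object of class `uhr_kappa` (see [cohen_kappa()]), with the
#'   weight matrix in `$weights`.
#' @export
#' @examples
#' tab <- matrix(c(51, 0, 0, 5, 92, 14, 1, 9, 40), 3, byrow = TRUE)
#' weighted_kappa(tab, scores = c(1, 0.84, 0))
weighted_kappa <- function(tab, weights = NULL, scores = NULL,
                           conf_level = 0.95) {
  tab <- as_crosstab(tab)
  k <- nrow(tab)
  if (is.null(weights)) {
    if (is.null(scores)) stop("supply either weights or scores")
    if (length(scores) != k) stop("need one score per category")
    rng <- diff(range(scores))
    if (rng == 0) stop("degenerate scores: all equal")
    weights <- 1 - abs(outer(scores, scores, "-")) / rng
  }
  weights <- unclass(as.matrix(weights))
  if (!all(dim(weights) == k)) stop("weight matrix dimension mismatch")
  if (!isTRUE(all.equal(weights, t(weights))) || any(abs(diag(weights) - 1) > 1e-12)) {
    stop("weights must be symmetric with unit diagonal")
  }
  n <- sum(tab)
  if (n == 0) stop("empty contingency table")
  p <- tab / n
  pr <- rowSums(p)
  pc <- colSums(p)
  po <- sum(weights * p)
  pe <- sum(weights * outer(pr, pc))
  if (1 - pe <= .Machine$double.eps) stop("kappa undefined: chance agreement is 1")
  kappa <- (po - pe) / (1 - pe)
  # weighted null SE (Fleiss, Cohen & Everitt)
  wi <- as.vector(weights %*% pc)   # row-wise expected weight
  wj <- as.vector(pr %*% weights)   # column-wise expected weight
  se0 <- sqrt(sum(outer(pr, pc) * (weights - outer(wi, wj, "+"))^2) - pe^2) /
    ((1 - pe) * sqrt(n))
  z <- kappa / se0
  zq <- qnorm(1 - (1 - conf_level) / 2)
  structure(list(
    po = po, pe = pe, kappa = kappa, se0 = se0, se_asymptotic = NA_real_,
    z = z, p_value = 2 * pnorm(-abs(z)),
    conf_low = kappa - zq * se0, conf_high = kappa + zq * se0,
    conf_level = conf_level, se_used = "null",
    pabak = NA_real_, n = n, k = k, table = tab,
    weighted = TRUE, weights = weights), class = "uhr_kappa")
}

#' McNemar-Bowker test of symmetry
#'
#' Tests marginal homogeneity of a square paired-outcome table via the
#' Bowker statistic `sum_{i<j} (n_ij - n_ji)^2 / (n_ij + n_ji)` over
#' discordant pairs with `n_ij + n_ji > 0`; degrees of freedom equal the
#' number of included pairs and the p value is the chi-square upper tail.
#' For 2 x 2 tables an exact binomial version (`exact = TRUE`) is available.
#'
#' @param tab A square contingency table.
#' @param exact Use the exact binomial McNemar test (2 x 2 tables only).
#' @return An object of class `uhr_bowker`: list with `statistic`, `df`,
#'   `p_value`, `method`, `pairs` (a tibble of the discordant pairs).
#' @export
#' @examples
#' tab <- matrix(c(51, 0, 0, 5, 92, 14, 1, 9, 40), 3, byrow = TRUE)
#' bowker_test(tab)
bowker_test <- function(tab, exact = FALSE) {
  tab <- as_crosstab(tab)
  k <- nrow(tab)
  lab <- rownames(tab)
  ij <- which(upper.tri(tab), arr.ind = TRUE)
  nij <- tab[ij]
  nji <- t(tab)[ij]
  keep <- nij + nji > 0
  pairs <- tibble(
    a = lab[ij[, 1]], b = lab[ij[, 2]],
    n_ab = nij, n_ba = nji, included = keep)
  if (exact) {
    if (k != 2) stop("exact test only available for 2 x 2 tables")
    if (!any(keep)) {
      return(structure(list(statistic = NA_real_, df = NA_real_, p_value = 1,
                            method = "exact McNemar (binomial)", pairs = pairs),
                       class = "uhr_bowker"))
    }
    p <- binom.test(nij[keep], nij[keep] + nji[keep], 0.5)$p.value
    return(structure(list(statistic = NA_real_, df = NA_real_, p_value = p,
                          method = "exact McNemar (binomial)", pairs = pairs),
                     class = "uhr_bowker"))
  }
  stat <- sum((nij[keep] - nji[keep])^2 / (nij[keep] + nji[keep]))
  df <- sum(keep)
  p <- if (df == 0) 1 else pchisq(stat, df, lower.tail = FALSE)
  structure(list(statistic = stat, df = df, p_value = p,
                 method = "McNemar-Bowker chi-square symmetry test",
                 pairs = pairs), class = "uhr_bowker")
}

#' Expected counts and adjusted residuals under independence
#'
#' Computes independence expected counts `e_ij = n_i. n_.j / N` and the
#' adjusted (standardized) residuals
#' `r_ij = (n_ij - e_ij) / sqrt(e_ij (1 - p_i.)(1 - p_.j))`. A cell with
#' `|r| > 3.29` deviates from independence at about p < 0.001 (two-sided,
#' multiplicity-corrected convention).
#'
#' @param tab A square contingency table with positive marginals.
#' @param threshold Flagging threshold on `|r|` (default 3.29).
#' @return An object of class `uhr_residuals`: list with matrices
#'   `expected` and `residuals`, `min_expected`, `threshold` and the table.
#'   `tidy()` returns one row per cell.
#' @export
#' @examples
#' tab <- matrix(c(51, 0, 0, 5, 92, 14, 1, 9, 40), 3, byrow = TRUE)
#' adjusted_residuals(tab)
adjusted_residuals <- function(tab, threshold = 3.29) {
  tab <- as_crosstab(tab)
  n <- sum(tab)
  rs <- rowSums(tab)
  cs <- colSums(tab)
  if (any(rs == 0)) stop("zero row marginal: ", rownames(tab)[which(rs == 0)[1]])
  if (any(cs == 0)) stop("zero column marginal: ", colnames(tab)[which(cs == 0)[1]])
  e <- outer(rs, cs) / n
  r <- (tab - e) / sqrt(e * outer(1 - rs / n, 1 - cs / n))
  structure(list(expected = e, residuals = r, min_expected = min(e),
                 threshold = threshold, table = tab),
            class = "uhr_residuals")
}

#' Diagnostic accuracy of predicted versus observed outcomes
#'
#' Binarizes the labels on `positive_class` versus the rest, computes
#' sensitivity, specificity and the single-threshold ROC area
#' `(sensitivity + specificity) / 2`, and computes kappa, PABAK and percent
#' agreement on the full multi-class table. A rate with an empty denominator
#' (no observed positives/negatives) is reported as `NA`.
#'
#' @param predicted,observed Paired label vectors or factors.
#' @param positive_class The label treated as positive (default
#'   `"Psychosis"`).
#' @return A one-row tibble: `sensitivity`, `specificity`, `roc_area`,
#'   `kappa`, `pabak`, `percent_agreement`, `n`.
#' @export
#' @examples
#' accuracy_metrics(rep(c("Psychosis", "UHR+"), c(28, 65)),
#'                  rep(c("Psychosis", "UHR+", "Psychosis", "UHR+"),
#'                      c(26, 2, 5, 60)))
accuracy_metrics <- function(predicted, observed, positive_class = "Psychosis") {
  predicted <- as.character(predicted)
  observed <- as.character(observed)
  if (length(predicted) != length(observed)) stop("length mismatch")
  ok <- !is.na(predicted) & !is.na(observed)
  predicted <- predicted[ok]
  observed <- observed[ok]
  if (!length(predicted)) stop("no complete prediction/observation pairs")
  if (!positive_class %in% c(predicted, observed)) {
    stop("positive_class not present in label set")
  }
  pos_p <- predicted == positive_class
  pos_o <- observed == positive_class
  tp <- sum(pos_p & pos_o)
  fn <- sum(!pos_p & pos_o)
  fp <- sum(pos_p & !pos_o)
  tn <- sum(!pos_p & !pos_o)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (fp + tn > 0) tn / (fp + tn) else NA_real_
  roc <- if (is.na(sens) || is.na(spec)) NA_real_ else (sens + spec) / 2
  tab <- outcome_crosstab(factor(predicted), factor(observed))
  kk <- tryCatch(cohen_kappa(tab), error = function(e) NULL)
  tibble(
    sensitivity = sens, specificity = spec, roc_area = roc,
    kappa = if (is.null(kk)) NA_real_ else kk$kappa,
    pabak = if (is.null(kk)) NA_real_ else kk$pabak,
    percent_agreement = 100 * mean(predicted == observed),
    n = length(predicted))
}
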
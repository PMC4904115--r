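# Tabular input/output: cohort CSV (one row per subject, booleans 0/1,
# empty cell = unknown), contingency-table CSV (labelled square matrix),
# and per-subject result reports with a sidecar text summary.

#' Read a cohort CSV
#'
#' Parses a UTF-8, comma-separated cohort file in the schema of
#' [cohort_columns()]. Missing required columns are a fatal error naming the
#' column; unknown columns are dropped with a warning; rows violating the
#' rating-scale invariants (see [validate_cohort()]) are excluded with a
#' warning and reported in the `violations` attribute of the result.
#' Boolean columns accept 0/1/TRUE/FALSE; empty cells parse to `NA`
#' ("unknown"). Parsing is locale-independent (decimal point).
#'
#' @param path Path to the CSV file.
#' @return A cohort tibble with attribute `violations` (a tibble as
#'   returned by [validate_cohort()]).
#' @export
read_cohort <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         locale = readr::locale(decimal_mark = "."),
                         progress = FALSE, show_col_types = FALSE)
  required <- cohort_columns()
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(raw), required)
  if (length(extra)) {
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "))
  }
  raw <- raw[required]
  out <- tibble(subject_id = raw$subject_id)
  for (col in setdiff(required, "subject_id")) {
    x <- raw[[col]]
    x[x == ""] <- NA
    if (col %in% cohort_bool_cols) {
      v <- rep(NA, length(x))
      v[x %in% c("1", "TRUE", "true")] <- TRUE
      v[x %in% c("0", "FALSE", "false")] <- FALSE
      bad <- !is.na(x) & is.na(v)
      if (any(bad)) stop("column ", col, ": unparseable boolean value '",
                         x[bad][1], "'")
      out[[col]] <- v
    } else {
      v <- suppressWarnings(as.numeric(x))
      bad <- !is.na(x) & is.na(v)
      if (any(bad)) stop("column ", col, ": unparseable numeric value '",
                         x[bad][1], "' (use a decimal point)")
      out[[col]] <- v
    }
  }
  viol <- validate_cohort(out)
  if (nrow(viol)) {
    warning("excluding ", length(unique(viol$row)), " row(s) with violations: ",
            paste(utils::head(paste0("row ", viol$row, " ", viol$field, " (",
                                     viol$rule, ")"), 5), collapse = "; "))
    out <- out[-unique(viol$row), ]
  }
  attr(out, "violations") <- viol
  out
}

#' Write a cohort CSV
#'
#' Writes a cohort tibble in the schema of [cohort_columns()] (booleans as
#' 0/1, unknowns as empty cells). Columns outside the schema are dropped.
#'
#' @param cohort A cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- as_tibble(cohort)[intersect(cohort_columns(), names(cohort))]
  for (col in intersect(cohort_bool_cols, names(cohort))) {
    cohort[[col]] <- as.integer(cohort[[col]])
  }
  readr::write_csv(cohort, path, na = "")
  invisible(path)
}

#' Read a labelled contingency-table CSV
#'
#' Expects a (k+1) x (k+1) layout: a header row of category labels and a
#' first column of the same labels, with nonnegative counts in the body.
#'
#' @param path Path to the CSV file.
#' @return A labelled square numeric matrix.
#' @export
read_contingency <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  labels <- as.character(d[[1]])
  m <- as.matrix(d[-1])
  storage.mode(m) <- "double"
  rownames(m) <- labels
  if (!identical(labels, colnames(m))) {
    stop("row and column labels must be identical")
  }
  as_crosstab(m)
}

#' Write a labelled contingency-table CSV
#'
#' @param tab A square labelled matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contingency <- function(tab, path) {
  tab <- as_crosstab(tab)
  d <- bind_cols(tibble(outcome = rownames(tab)), as_tibble(as.data.frame(tab)))
  readr::write_csv(d, path)
  invisible(path)
}

#' Write a per-subject results report
#'
#' Writes a CSV of per-subject outcomes (classification or conversion
#' results; list-columns such as rule traces are flattened to
#' `criterion=pass` strings) and, when the results carry paired
#' observed/predicted outcomes or when a second result set is supplied, a
#' sidecar `<path>.summary.txt` with the cohort-level agreement statistics
#' (percent agreement, kappa with z/CI, PABAK, Bowker test, minimum
#' expected count).
#'
#' @param results A classification tibble ([classify_caarms()],
#'   [classify_sips()]) or a conversion table ([convert_cohort()]).
#' @param path Output CSV path.
#' @param compare_with Optional second classification tibble paired by row;
#'   agreement statistics are computed between `results` and it.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, compare_with = NULL) {
  results <- as_tibble(results)
  if (nrow(results) == 0) stop("empty results: nothing to report")
  flat <- results
  if ("rule_trace" %in% names(flat)) {
    flat$rule_trace <- map_chr(flat$rule_trace, function(tr) {
      paste(paste0(tr$criterion, "=", ifelse(tr$passed, "pass", "fail")),
            collapse = ";")
    })
  }
  for (col in names(flat)) {
    if (is.factor(flat[[col]])) flat[[col]] <- as.character(flat[[col]])
  }
  readr::write_csv(flat, path, na = "")

  pair <- NULL
  if (!is.null(compare_with)) {
    pair <- list(a = outcome_labels(results), b = outcome_labels(compare_with))
  } else if (all(c("observed", "predicted") %in% names(results))) {
    ok <- !is.na(results$observed) & !is.na(results$predicted)
    if (any(ok)) pair <- list(a = results$observed[ok], b = results$predicted[ok])
  }
  if (!is.null(pair)) {
    tab <- outcome_crosstab(pair$a, pair$b)
    lines <- c(sprintf("N = %d", as.integer(sum(tab))), "")
    kk <- tryCatch(cohen_kappa(tab), error = function(e) NULL)
    if (!is.null(kk)) {
      lines <- c(lines,
        sprintf("percent overall agreement = %.2f%%", 100 * kk$po),
        sprintf("expected agreement by chance = %.2f%%", 100 * kk$pe),
        sprintf("kappa = %.3f (Z = %.2f, p = %.3g, 95%% CI %.3f to %.3f)",
                kk$kappa, kk$z, kk$p_value, kk$conf_low, kk$conf_high),
        sprintf("PABAK = %.3f", kk$pabak))
    }
    bw <- tryCatch(bowker_test(tab), error = function(e) NULL)
    if (!is.null(bw)) {
      lines <- c(lines, sprintf("McNemar-Bowker chi-square = %.3f (df %d, p = %.3g)",
                                bw$statistic, as.integer(bw$df), bw$p_value))
    }
    rr <- tryCatch(adjusted_residuals(tab), error = function(e) NULL)
    if (!is.null(rr)) {
      lines <- c(lines, sprintf("minimum expected count = %.2f", rr$min_expected))
    }
    writeLines(lines, paste0(path, ".summary.txt"))
  }
  invisible(path)
}
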
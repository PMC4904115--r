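# broom-style tidy()/glance() methods and ggplot2 autoplots for the
# result objects. tidy() and glance() generics are defined here so the
# package does not depend on broom; they dispatch to broom's if loaded.

#' Turn a result object into a tidy tibble
#'
#' @param x A result object (`uhr_kappa`, `uhr_bowker`, `uhr_residuals`,
#'   `uhr_linking`).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row model summary of a result object
#'
#' @inheritParams tidy
#' @return A one-row tibble.
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @export
tidy.uhr_kappa <- function(x, ...) {
  tibble(
    term = if (x$weighted) "weighted kappa" else "kappa",
    estimate = x$kappa, std.error = x$se0, statistic = x$z,
    p.value = x$p_value, conf.low = x$conf_low, conf.high = x$conf_high)
}

#' @export
glance.uhr_kappa <- function(x, ...) {
  tibble(
    percent_agreement = 100 * x$po, percent_chance = 100 * x$pe,
    kappa = x$kappa, z = x$z, p.value = x$p_value,
    conf.low = x$conf_low, conf.high = x$conf_high,
    pabak = x$pabak, n = x$n, k = x$k)
}

#' @export
print.uhr_kappa <- function(x, digits = 3, ...) {
  cat(if (x$weighted) "Weighted kappa" else "Cohen's kappa",
      sprintf("(%d x %d table, N = %d)\n", x$k, x$k, as.integer(x$n)))
  cat(sprintf("  observed agreement %.2f%%, chance agreement %.2f%%\n",
              100 * x$po, 100 * x$pe))
  cat(sprintf("  kappa = %.*f (Z = %.2f, p = %.3g, %g%% CI %.3f to %.3f)\n",
              digits, x$kappa, x$z, x$p_value, 100 * x$conf_level,
              x$conf_low, x$conf_high))
  if (!is.na(x$pabak)) cat(sprintf("  PABAK = %.*f\n", digits, x$pabak))
  invisible(x)
}

#' @export
tidy.uhr_bowker <- function(x, ...) x$pairs

#' @export
glance.uhr_bowker <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p.value = x$p_value,
         method = x$method)
}

#' @export
print.uhr_bowker <- function(x, ...) {
  cat(x$method, "\n")
  if (!is.na(x$statistic)) {
    cat(sprintf("  chi-square = %.3f, df = %d, p = %.3g\n",
                x$statistic, as.integer(x$df), x$p_value))
  } else {
    cat(sprintf("  p = %.3g\n", x$p_value))
  }
  invisible(x)
}

#' @export
tidy.uhr_residuals <- function(x, ...) {
  lab_r <- rownames(x$table)
  lab_c <- colnames(x$table)
  idx <- expand.grid(row = seq_along(lab_r), col = seq_along(lab_c))
  tibble(
    row = lab_r[idx$row], col = lab_c[idx$col],
    observed = x$table[cbind(idx$row, idx$col)],
    expected = x$expected[cbind(idx$row, idx$col)],
    residual = x$residuals[cbind(idx$row, idx$col)],
    significant = abs(x$residuals[cbind(idx$row, idx$col)]) > x$threshold)
}

#' @export
glance.uhr_residuals <- function(x, ...) {
  tibble(min_expected = x$min_expected, threshold = x$threshold,
         n_significant = sum(abs(x$residuals) > x$threshold),
         n = sum(x$table))
}

#' @export
print.uhr_residuals <- function(x, ...) {
  cat("Adjusted residuals (|r| >", x$threshold, "flagged)\n")
  print(round(x$residuals, 1))
  cat(sprintf("minimum expected count %.2f\n", x$min_expected))
  invisible(x)
}

#' Plot adjusted residuals as a heat map
#'
#' @param object An `uhr_residuals` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot uhr_residuals
#' @export
autoplot.uhr_residuals <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                  fill = .data$residual)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%d\n(r = %.1f)", as.integer(.data$observed),
                      .data$residual))) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1) * max(abs(d$residual))) +
    ggplot2::labs(x = "instrument B outcome", y = "instrument A outcome",
                  fill = "adjusted\nresidual") +
    ggplot2::theme_minimal()
}

#' Plot paired-outcome counts as a heat map
#'
#' @param tab A square contingency table.
#' @return A ggplot.
#' @export
plot_crosstab <- function(tab) {
  tab <- as_crosstab(tab)
  d <- as_tibble(as.data.frame(as.table(tab)))
  names(d) <- c("row", "col", "count")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                  fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::labs(x = "instrument B outcome", y = "instrument A outcome") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
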
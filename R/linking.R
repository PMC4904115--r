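# Observed-score equipercentile linking between the CAARMS and SIPS
# severity/frequency scales. Discrete integer scores are continuized with
# the uniform-kernel convention: each score x spreads uniformly over
# [x - 0.5, x + 0.5), so the percentile-rank function is piecewise linear
# and invertible by interpolation (no presmoothing).

#' Build a discrete score distribution
#'
#' @param scores Integer scores observed (tallied), or `NULL` when `counts`
#'   are given directly.
#' @param counts Optional named or positional counts per score over `range`.
#' @param range Integer score range `c(min, max)`; defaults to the observed
#'   range of `scores` or `0:(length(counts)-1)`.
#' @return An object of class `score_distribution`: a tibble with columns
#'   `score` and `count` covering the full range.
#' @export
#' @examples
#' score_distribution(c(0, 1, 1, 1), range = c(0, 1))
#' score_distribution(counts = c(`0` = 50, `1` = 50))
score_distribution <- function(scores = NULL, counts = NULL, range = NULL) {
  if (is.null(scores) && is.null(counts)) stop("empty distribution")
  if (is.null(counts)) {
    scores <- scores[!is.na(scores)]
    if (!length(scores)) stop("empty distribution")
    if (any(scores != round(scores))) stop("scores must be integers")
    if (is.null(range)) range <- c(min(scores), max(scores))
    full <- seq(range[1], range[2])
    counts <- vapply(full, function(s) sum(scores == s), 0)
  } else {
    if (is.null(range)) {
      range <- if (!is.null(names(counts))) {
        as.numeric(c(names(counts)[1], names(counts)[length(counts)]))
      } else c(0, length(counts) - 1)
    }
    full <- seq(range[1], range[2])
    if (length(counts) != length(full)) stop("counts do not cover the range")
  }
  if (any(counts < 0)) stop("negative counts")
  if (sum(counts) == 0) stop("empty distribution")
  structure(tibble(score = full, count = as.numeric(counts)),
            class = c("score_distribution", class(tibble())))
}

#' Continuized percentile rank of a score
#'
#' The percentile-rank function of the continuized distribution: for a
#' value x falling in the interval of integer score s,
#' `P(x) = F(s - 1) + (x - (s - 0.5)) f(s)`, i.e. the cumulative proportion
#' below s plus the linear share of s's own probability mass. Clamped to
#' `[0, 1]` outside `[min - 0.5, max + 0.5]`.
#'
#' @param d A [score_distribution()].
#' @param x Numeric values on the score scale.
#' @return Proportions in `[0, 1]`.
#' @export
#' @examples
#' d <- score_distribution(counts = c(`0` = 1, `1` = 3))
#' percentile_rank(d, 1)  # 0.25 + 0.75 * 0.5 = 0.625
percentile_rank <- function(d, x) {
  stopifnot(inherits(d, "score_distribution"))
  f <- d$count / sum(d$count)
  cum <- cumsum(f)
  lo <- d$score[1]
  hi <- d$score[length(d$score)]
  vapply(x, function(xi) {
    if (is.na(xi)) return(NA_real_)
    if (xi <= lo - 0.5) return(0)
    if (xi >= hi + 0.5) return(1)
    s <- floor(xi + 0.5)            # integer interval containing xi
    i <- s - lo + 1
    below <- if (i > 1) cum[i - 1] else 0
    below + (xi - (s - 0.5)) * f[i]
  }, 0)
}

#' Inverse percentile rank (continuized quantile)
#'
#' Inverts [percentile_rank()] by linear interpolation within the score
#' interval containing the requested proportion; results clamp to
#' `[min - 0.5, max + 0.5]`. Where the requested rank falls in a flat
#' stretch of the CDF (zero-count scores), the midpoint of the flat stretch
#' is returned.
#'
#' @param d A [score_distribution()].
#' @param p Proportions in `[0, 1]`.
#' @return Values on the continuized score scale.
#' @export
score_from_rank <- function(d, p) {
  stopifnot(inherits(d, "score_distribution"))
  f <- d$count / sum(d$count)
  cum <- c(0, cumsum(f))
  edges <- c(d$score - 0.5, d$score[length(d$score)] + 0.5)
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_real_)
    if (pi <= 0) return(edges[1])
    if (pi >= 1) return(edges[length(edges)])
    i <- findInterval(pi, cum, rightmost.closed = TRUE)
    i <- min(max(i, 1L), length(f))
    if (f[i] > 0) {
      edges[i] + (pi - cum[i]) / f[i]
    } else {
      # flat CDF: return midpoint of the run of zero-mass scores
      j <- i
      while (j < length(f) && f[j] == 0) j <- j + 1
      (edges[i] + edges[j]) / 2
    }
  }, 0)
}

#' Equipercentile linking of one score scale to another
#'
#' Links each source score x to the target-scale value with the same
#' continuized percentile rank: `e(x) = Q_target(P_source(x))`, with Q the
#' interpolated inverse of the target percentile-rank function. Linked
#' values are clamped to `[target min - 0.5, target max + 0.5]` and are
#' monotone nondecreasing in x.
#'
#' @param source,target [score_distribution()] objects.
#' @param scores Integer source scores to link; defaults to the source range.
#' @param label Direction label stored with the table (e.g.
#'   `"P1 CAARMS to P1 SIPS severity"`).
#' @return An object of class `uhr_linking`: a tibble with columns `source`
#'   and `linked`, plus the label attribute.
#' @export
#' @examples
#' src <- score_distribution(counts = c(`0` = 50, `1` = 50))
#' tgt <- score_distribution(counts = c(`0` = 25, `1` = 75))
#' link_scores(src, tgt)
link_scores <- function(source, target, scores = NULL, label = NULL) {
  stopifnot(inherits(source, "score_distribution"),
            inherits(target, "score_distribution"))
  if (is.null(scores)) scores <- source$score
  linked <- score_from_rank(target, percentile_rank(source, scores))
  out <- tibble(source = scores, linked = linked)
  structure(out, label = label %||% "equipercentile linking",
            class = c("uhr_linking", class(out)))
}

#' @export
tidy.uhr_linking <- function(x, ...) {
  tibble(direction = attr(x, "label"), source = x$source, linked = x$linked)
}

#' Plot a linking table
#'
#' @param object An `uhr_linking` table.
#' @param ... Unused.
#' @return A ggplot of linked score against source score, with the identity
#'   line for reference.
#' @method autoplot uhr_linking
#' @export
autoplot.uhr_linking <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$source, y = .data$linked)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(title = attr(object, "label"),
                  x = "source score", y = "linked target score") +
    ggplot2::theme_minimal()
}

#' Analytic SIPS frequency recode for linking
#'
#' Recodes the standard SIPS frequency score (0-3) onto the analytic bands
#' used for score linking: code 1 is the "at least 1 h/day, at least
#' 4 days/week" band (standard score 3), code 2 is "at least several
#' minutes/day, at least once/month" (standard score 1), code 3 is "at
#' least once/week" (standard score 2) and code 0 is none of the above.
#' This recode is used only in the linking pathway, never for diagnosis;
#' it is not an involution.
#'
#' @param freq Integer SIPS frequency scores 0-3.
#' @return Recoded integer scores 0-3.
#' @export
#' @examples
#' recode_sips_frequency_for_linking(0:3)
recode_sips_frequency_for_linking <- function(freq) {
  if (any(!is.na(freq) & (freq < 0 | freq > 3 | freq != round(freq)))) {
    stop("frequency out of [0,3]")
  }
  c(0L, 2L, 3L, 1L)[freq + 1L]
}

linking_domains <- list(
  list(caarms = 1L, sips = 1L, lab = "P1 CAARMS / P1 SIPS"),
  list(caarms = 2L, sips = 2L, lab = "P2 CAARMS / P2 SIPS"),
  list(caarms = 2L, sips = 3L, lab = "P2 CAARMS / P3 SIPS"),
  list(caarms = 2L, sips = NA, lab = "P2 CAARMS / max(P2,P3) SIPS"),
  list(caarms = 3L, sips = 4L, lab = "P3 CAARMS / P4 SIPS"),
  list(caarms = 4L, sips = 5L, lab = "P4 CAARMS / P5 SIPS")
)

#' Equipercentile linking report for a dual-rated cohort
#'
#' Builds the full set of severity and frequency linking tables between the
#' matched CAARMS/SIPS domains of a cohort rated on both instruments:
#' P1-P1, P2 CAARMS to P2 SIPS and to P3 SIPS, the highest of SIPS P2/P3
#' back to CAARMS P2, P3 CAARMS-P4 SIPS and P4 CAARMS-P5 SIPS, in both
#' directions (severity on the shared 0-6 scale; frequency from the CAARMS
#' 0-6 scale to the analytically recoded SIPS 0-3 scale, see
#' [recode_sips_frequency_for_linking()]).
#'
#' @param cohort A data frame in the cohort schema rated on both
#'   instruments.
#' @return A named list of `uhr_linking` tables.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 100, seed = 1))
#' names(build_linking_report(cohort))
build_linking_report <- function(cohort) {
  cohort <- as_tibble(cohort)
  if (nrow(cohort) == 0) stop("empty cohort")
  if (!any(has_caarms(cohort) & has_sips(cohort))) {
    stop("cohort must be rated on both instruments")
  }
  both <- cohort[has_caarms(cohort) & has_sips(cohort), ]
  sips_col <- function(i, what) both[[paste0("sips_p", i, "_", what)]]
  dist_of <- function(x, range) {
    x <- x[!is.na(x)]
    if (!length(x)) x <- range[1]  # degenerate but defined
    score_distribution(x, range = range)
  }
  out <- list()
  for (dom in linking_domains) {
    c_sev <- dist_of(both[[paste0("caarms_p", dom$caarms, "_severity")]], c(0, 6))
    c_frq <- dist_of(both[[paste0("caarms_p", dom$caarms, "_frequency")]], c(0, 6))
    if (is.na(dom$sips)) {  # max of SIPS P2/P3, frequency of the higher
      s2 <- sips_col(2, "severity")
      s3 <- sips_col(3, "severity")
      s_sev_v <- pmax(ifelse(is.na(s2), 0, s2), ifelse(is.na(s3), 0, s3))
      use3 <- ifelse(is.na(s3), 0, s3) > ifelse(is.na(s2), 0, s2)
      s_frq_v <- ifelse(use3, sips_col(3, "frequency"), sips_col(2, "frequency"))
    } else {
      s_sev_v <- sips_col(dom$sips, "severity")
      s_frq_v <- sips_col(dom$sips, "frequency")
    }
    s_sev <- dist_of(s_sev_v, c(0, 6))
    s_frq <- dist_of(recode_sips_frequency_for_linking(s_frq_v), c(0, 3))
    lab <- dom$lab
    out[[paste(lab, "severity caarms2sips")]] <-
      link_scores(c_sev, s_sev, label = paste(lab, "severity, CAARMS to SIPS"))
    out[[paste(lab, "severity sips2caarms")]] <-
      link_scores(s_sev, c_sev, label = paste(lab, "severity, SIPS to CAARMS"))
    out[[paste(lab, "frequency caarms2sips")]] <-
      link_scores(c_frq, s_frq, label = paste(lab, "frequency, CAARMS to SIPS"))
    out[[paste(lab, "frequency sips2caarms")]] <-
      link_scores(s_frq, c_frq, label = paste(lab, "frequency, SIPS to CAARMS"))
  }
  out
}
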
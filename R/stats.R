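#' Chi-square test on a contingency table of cohort outcomes
#'
#' Pearson chi-square on an r x k table of counts (condition x outcome),
#' without continuity correction by default, as used to compare categorical
#' adhesion/tethering frequencies between conditions.
#'
#' @param table Matrix (or 2-column data.frame) of non-negative integer
#'   counts.
#' @param correct Apply the Yates continuity correction (2 x 2 only).
#' @return List of class `test_result`: `method`, `statistic`, `df`,
#'   `p_value`, `tail`, `stars`, `warning` (non-NULL when any expected cell
#'   count is below 5).
#' @export
chi_square_test <- function(table, correct = FALSE) {
  m <- as.matrix(table)
  if (any(m < 0) || any(m != round(m)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero marginal total", call. = FALSE)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  warn <- if (any(expected < 5))
    "expected cell count below 5; chi-square approximation may be poor"
  else NULL
  res <- suppressWarnings(stats::chisq.test(m, correct = correct))
  structure(list(method = if (correct) "Pearson chi-square (Yates-corrected)"
                          else "Pearson chi-square",
                 statistic = unname(res$statistic),
                 df = unname(res$parameter),
                 p_value = unname(res$p.value),
                 tail = "upper", stars = annotate_stars(res$p.value),
                 warning = warn),
            class = "test_result")
}

#' One-tailed unpaired Student t test
#'
#' Classical pooled-variance unpaired t test (Welch variant behind a flag)
#' with a one-tailed p value in the stated direction, as used to compare
#' rolling-velocity distributions between conditions.
#'
#' @param sample_a,sample_b Numeric samples, each of length >= 2.
#' @param direction `"a_greater"` or `"b_greater"`: the alternative
#'   hypothesis direction.
#' @param welch Use the Welch (unequal-variance) variant.
#' @return A `test_result` list (`statistic` is t computed as a - b,
#'   `df`, one-tailed `p_value`, `stars`). With zero pooled variance and
#'   equal means, `p_value = 0.5` by convention (flagged in `warning`).
#' @export
one_tailed_t_test <- function(sample_a, sample_b,
                              direction = c("a_greater", "b_greater"),
                              welch = FALSE) {
  direction <- match.arg(direction)
  if (length(sample_a) < 2 || length(sample_b) < 2)
    stop("each sample needs n >= 2", call. = FALSE)
  if (stats::var(sample_a) == 0 && stats::var(sample_b) == 0) {
    if (mean(sample_a) == mean(sample_b)) {
      return(structure(list(method = "one-tailed unpaired Student t",
                            statistic = 0,
                            df = length(sample_a) + length(sample_b) - 2,
                            p_value = 0.5, tail = "one",
                            stars = "ns",
                            warning = "zero variance in both samples"),
                       class = "test_result"))
    }
    stop("degenerate samples: zero variance with unequal means",
         call. = FALSE)
  }
  alt <- if (direction == "a_greater") "greater" else "less"
  res <- stats::t.test(sample_a, sample_b, alternative = alt,
                       var.equal = !welch)
  structure(list(method = if (welch) "one-tailed Welch t"
                          else "one-tailed unpaired Student t",
                 statistic = unname(res$statistic),
                 df = unname(res$parameter),
                 p_value = unname(res$p.value),
                 tail = "one", stars = annotate_stars(res$p.value),
                 warning = NULL),
            class = "test_result")
}

#' Median fold change between two samples
#'
#' The reporting quantity for rolling-velocity shifts: the ratio of sample
#' medians and the corresponding percent change.
#'
#' @param sample_a,sample_b Non-empty numeric samples; `median(sample_b)`
#'   must be non-zero.
#' @return List with `ratio` = median(a)/median(b) and `percent_change` =
#'   100 * (median(a) - median(b)) / median(b).
#' @export
median_fold_change <- function(sample_a, sample_b) {
  if (length(sample_a) == 0 || length(sample_b) == 0)
    stop("samples must be non-empty", call. = FALSE)
  ma <- stats::median(sample_a); mb <- stats::median(sample_b)
  if (mb == 0) stop("median of reference sample is zero; ratio undefined",
                    call. = FALSE)
  list(ratio = ma / mb, percent_change = 100 * (ma - mb) / mb)
}

#' Ratio of two proportions with a normal-theory confidence interval
#'
#' Katz log-ratio interval for the ratio of two binomial proportions
#' (x_a/n_a) / (x_b/n_b); used to put a confidence interval on fold changes
#' of adhesion/tethering percentages.
#'
#' @param x_a,n_a Successes and trials in condition A.
#' @param x_b,n_b Successes and trials in condition B.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `ratio`, `lower`, `upper`.
#' @export
proportion_ratio_ci <- function(x_a, n_a, x_b, n_b, conf_level = 0.95) {
  if (min(n_a, n_b) <= 0 || x_b <= 0 || x_a < 0)
    stop("need positive denominators and x_b > 0", call. = FALSE)
  rr <- (x_a / n_a) / (x_b / n_b)
  if (x_a == 0) return(list(ratio = 0, lower = 0, upper = Inf))
  se <- sqrt(1 / x_a - 1 / n_a + 1 / x_b - 1 / n_b)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(ratio = rr, lower = rr * exp(-z * se), upper = rr * exp(z * se))
}

#' Significance stars for a p value
#'
#' Strict-inequality thresholds: `ns` for p >= 0.05, `*` for p < 0.05,
#' `**` for p < 0.01, `***` for p < 0.001 (boundary values get the weaker
#' label).
#'
#' @param p p value in [0, 1].
#' @return One of `"ns"`, `"*"`, `"**"`, `"***"` (vectorized).
#' @export
annotate_stars <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p must lie in [0, 1]", call. = FALSE)
  ifelse(p < 0.001, "***",
         ifelse(p < 0.01, "**",
                ifelse(p < 0.05, "*", "ns")))
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %.4g, p = %.4g (%s)\n",
              x$method, x$statistic, x$df, x$p_value, x$stars))
  if (!is.null(x$warning)) cat("  note:", x$warning, "\n")
  invisible(x)
}

#' Compare two cohort summaries at one shear level
#'
#' Chi-square comparisons of adhesion and tethering counts (classified vs
#' not, per condition) and, when both cohorts have rolling tracks, a
#' one-tailed t test on rolling velocities.
#'
#' @param summary_a,summary_b One-row [summarize_cohort()] outputs.
#' @param velocities_a,velocities_b Optional rolling-velocity vectors for
#'   the t test.
#' @param velocity_direction Direction passed to [one_tailed_t_test()].
#' @return data.frame with one row per comparison: `comparison`, `method`,
#'   `statistic`, `df`, `p_value`, `stars`.
#' @export
compare_cohorts <- function(summary_a, summary_b,
                            velocities_a = NULL, velocities_b = NULL,
                            velocity_direction = "b_greater") {
  rows <- list()
  for (what in c("adhesion", "tethering")) {
    cnt <- if (what == "adhesion") c(summary_a$n_adhere, summary_b$n_adhere)
           else c(summary_a$n_tether, summary_b$n_tether)
    tot <- c(summary_a$n_total, summary_b$n_total)
    tab <- cbind(classified = cnt, not_classified = tot - cnt)
    res <- tryCatch(chi_square_test(tab), error = function(e) NULL)
    if (!is.null(res))
      rows[[length(rows) + 1]] <- data.frame(
        comparison = what, method = res$method, statistic = res$statistic,
        df = res$df, p_value = res$p_value, stars = res$stars,
        stringsAsFactors = FALSE)
  }
  if (!is.null(velocities_a) && !is.null(velocities_b) &&
      length(velocities_a) >= 2 && length(velocities_b) >= 2) {
    res <- one_tailed_t_test(velocities_a, velocities_b,
                             direction = velocity_direction)
    rows[[length(rows) + 1]] <- data.frame(
      comparison = "rolling_velocity", method = res$method,
      statistic = res$statistic, df = res$df, p_value = res$p_value,
      stars = res$stars, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
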
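# Method-comparison and reliability statistics: Pearson correlation with
# exact t-based p-value, Bland-Altman 95% limits of agreement, and
# Shrout-Fleiss intraclass correlation coefficients with F-based confidence
# intervals.

#' Pearson product-moment correlation with exact two-sided p
#'
#' The p-value comes from the exact transform
#' `t = r sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom. The
#' correlation-strength label follows the conventional bands (see
#' [strength_category()]).
#'
#' @param x,y Paired numeric vectors, equal length, `n >= 3`, each with
#'   nonzero variance.
#' @return An object of class `correlation_result`: `r`, `p_two_sided`,
#'   `n`, `category`.
#' @export
pearson <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 3L) stop("pearson requires n >= 3 pairs", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("x and y must be finite", call. = FALSE)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  structure(list(r = r, p_two_sided = p, n = n,
                 category = strength_category(r)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (%s), n = %d, two-sided p = %.4g\n",
              x$r, x$category, x$n, x$p_two_sided))
  invisible(x)
}

#' Correlation-strength category
#'
#' Conventional bands on |r|: 0.00-0.20 slight, 0.21-0.40 fair, 0.41-0.60
#' moderate, 0.61-0.80 substantial, 0.81-1.00 almost perfect. Band edges
#' belong to the lower band (0.20 is still "slight").
#'
#' @param r Correlation coefficient, `|r| <= 1`.
#' @return One of `"slight"`, `"fair"`, `"moderate"`, `"substantial"`,
#'   `"almost perfect"`.
#' @export
strength_category <- function(r) {
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r)) {
    stop("r must be a finite scalar", call. = FALSE)
  }
  a <- abs(r)
  if (a > 1 + 1e-12) stop("|r| must not exceed 1", call. = FALSE)
  if (a <= 0.20) "slight"
  else if (a <= 0.40) "fair"
  else if (a <= 0.60) "moderate"
  else if (a <= 0.80) "substantial"
  else "almost perfect"
}

.ba_result <- function(mean_diff, sd_diff, n) {
  structure(list(mean_diff_deg = mean_diff,
                 sd_diff_deg = sd_diff,
                 upper_loa_deg = mean_diff + 1.96 * sd_diff,
                 lower_loa_deg = mean_diff - 1.96 * sd_diff,
                 half_width_deg = 1.96 * sd_diff,
                 n = n),
            class = "bland_altman")
}

#' Bland-Altman limits of agreement from paired measurements
#'
#' Differences are taken as `x - y` (test method minus reference). Limits
#' use the sample SD (n - 1 denominator) and the fixed 1.96 multiplier:
#' mean difference +/- 1.96 SD.
#'
#' @param x Test-method measurements (degrees).
#' @param y Reference measurements (degrees), same length, `n >= 2`.
#' @return An object of class `bland_altman`: `mean_diff_deg`,
#'   `sd_diff_deg`, `upper_loa_deg`, `lower_loa_deg`, `half_width_deg`, `n`.
#' @export
bland_altman <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) {
    stop("x and y must have equal length", call. = FALSE)
  }
  if (length(x) < 2L) stop("bland_altman requires n >= 2 pairs", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("x and y must be finite", call. = FALSE)
  }
  d <- x - y
  .ba_result(mean(d), stats::sd(d), length(d))
}

#' Bland-Altman limits from a reported mean and SD of differences
#'
#' For recomputing limits when only summary statistics are available (as
#' printed in published agreement tables); `n` is unset.
#'
#' @param mean_diff Mean of differences (degrees).
#' @param sd_diff SD of differences (degrees), `>= 0`.
#' @return A `bland_altman` object with `n = NA`.
#' @export
limits_from_summary <- function(mean_diff, sd_diff) {
  if (!is.numeric(mean_diff) || length(mean_diff) != 1L ||
      !is.finite(mean_diff)) {
    stop("mean_diff must be a finite scalar", call. = FALSE)
  }
  if (!is.numeric(sd_diff) || length(sd_diff) != 1L || !is.finite(sd_diff) ||
      sd_diff < 0) {
    stop("sd_diff must be a finite non-negative scalar", call. = FALSE)
  }
  .ba_result(mean_diff, sd_diff, NA_integer_)
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: mean diff %.2f deg, SD %.2f deg\n",
              x$mean_diff_deg, x$sd_diff_deg))
  cat(sprintf("  95%% LOA [%.2f, %.2f] deg (half-width %.2f)",
              x$lower_loa_deg, x$upper_loa_deg, x$half_width_deg))
  if (!is.na(x$n)) cat(sprintf(", n = %d", x$n))
  cat("\n")
  invisible(x)
}
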
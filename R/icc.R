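# Intraclass correlation coefficients (Shrout-Fleiss conventions) with
# F-based 95% confidence intervals (McGraw-Wong construction).
#
# Data layout: one row per target (here: nominal angle or subject), one
# column per measurement (repetition or rater). Mean squares come from the
# standard ANOVA decomposition via stats::lm/anova:
#   one-way:      value ~ target            -> BMS, WMS
#   two-way:      value ~ target + rater    -> BMS, JMS, EMS
#
#   ICC(1,1) = (BMS - WMS) / (BMS + (k-1) WMS)
#   ICC(1,k) = (BMS - WMS) / BMS
#   ICC(2,1) = (BMS - EMS) / (BMS + (k-1) EMS + k (JMS - EMS) / n)
#   ICC(2,k) = (BMS - EMS) / (BMS + (JMS - EMS) / n)

.icc_mean_squares <- function(data) {
  n <- nrow(data); k <- ncol(data)
  long <- data.frame(value = as.vector(data),
                     target = factor(rep(seq_len(n), times = k)),
                     rater = factor(rep(seq_len(k), each = n)))
  # only the mean squares are used; anova.lm's F-test warning on a
  # perfect fit (zero residual) does not apply here
  a1 <- suppressWarnings(stats::anova(stats::lm(value ~ target, data = long)))
  a2 <- suppressWarnings(stats::anova(stats::lm(value ~ target + rater,
                                                data = long)))
  list(n = n, k = k,
       bms = a1["target", "Mean Sq"],
       wms = a1["Residuals", "Mean Sq"],
       jms = a2["rater", "Mean Sq"],
       ems = a2["Residuals", "Mean Sq"])
}

.clamp_unit <- function(x) pmin(1, pmax(-1, x))

# CI for the one-way model via the F ratio BMS/WMS.
.icc1_ci <- function(ms, unit, conf_level) {
  alpha <- 1 - conf_level
  df1 <- ms$n - 1L
  df2 <- ms$n * (ms$k - 1L)
  if (ms$wms <= 0) return(c(1, 1))  # perfect agreement, interval degenerate
  fobs <- ms$bms / ms$wms
  fl <- fobs / stats::qf(1 - alpha / 2, df1, df2)
  fu <- fobs * stats::qf(1 - alpha / 2, df2, df1)
  if (unit == "single") {
    c((fl - 1) / (fl + ms$k - 1), (fu - 1) / (fu + ms$k - 1))
  } else {
    c(1 - 1 / fl, 1 - 1 / fu)
  }
}

# CI for the two-way random model (agreement), Satterthwaite df for the
# denominator as in McGraw & Wong.
.icc2_ci <- function(ms, est_single, unit, conf_level) {
  alpha <- 1 - conf_level
  n <- ms$n; k <- ms$k
  if (ms$ems <= 0 && ms$jms <= 0) return(c(1, 1))
  r0 <- est_single
  fj <- if (ms$ems > 0) ms$jms / ms$ems else Inf
  vn <- (k - 1) * (n - 1) *
    ((k * r0 * fj + n * (1 + (k - 1) * r0) - k * r0))^2
  vd <- (n - 1) * k^2 * r0^2 * fj^2 +
    (n * (1 + (k - 1) * r0) - k * r0)^2
  v <- vn / vd
  if (!is.finite(v) || v <= 0) v <- (n - 1) * (k - 1)
  f3u <- stats::qf(1 - alpha / 2, n - 1, v)
  f3l <- stats::qf(1 - alpha / 2, v, n - 1)
  lo <- n * (ms$bms - f3u * ms$ems) /
    (f3u * (k * ms$jms + (k * n - k - n) * ms$ems) + n * ms$bms)
  hi <- n * (f3l * ms$bms - ms$ems) /
    (k * ms$jms + (k * n - k - n) * ms$ems + n * f3l * ms$bms)
  if (unit == "average_k") {
    lo <- lo * k / (1 + (k - 1) * lo)
    hi <- hi * k / (1 + (k - 1) * hi)
  }
  c(lo, hi)
}

#' Intraclass correlation coefficient with 95% confidence interval
#'
#' Shrout-Fleiss estimates from the ANOVA mean squares: one-way random
#' (each target rated by a different set of raters; intra-rater designs) or
#' two-way random (same raters for all targets; inter-rater designs), in
#' single-measurement or average-of-k form. Confidence intervals use the
#' F-distribution construction.
#'
#' @param data Numeric matrix, `n >= 2` targets (rows) by `k >= 2`
#'   measurements (columns), no missing cells.
#' @param model `"oneway"` or `"twoway_random"`.
#' @param unit `"single"` or `"average_k"`.
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `icc_result`: `model`, `unit`, `k`, `n`,
#'   `estimate`, `ci95 = c(lo, hi)` (clamped to \[-1, 1\]), and the mean
#'   squares used.
#' @export
icc <- function(data, model = c("oneway", "twoway_random"),
                unit = c("single", "average_k"), conf_level = 0.95) {
  model <- match.arg(model)
  unit <- match.arg(unit)
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("data must be numeric", call. = FALSE)
  if (anyNA(data)) stop("missing cells are not supported", call. = FALSE)
  n <- nrow(data); k <- ncol(data)
  if (n < 2L || k < 2L) {
    stop("icc requires at least 2 targets and 2 measurements", call. = FALSE)
  }
  if (stats::var(rowMeans(data)) == 0) {
    stop("ICC undefined: zero between-target variance", call. = FALSE)
  }
  ms <- .icc_mean_squares(data)

  if (model == "oneway") {
    est_single <- (ms$bms - ms$wms) / (ms$bms + (k - 1) * ms$wms)
    est <- if (unit == "single") est_single else (ms$bms - ms$wms) / ms$bms
    ci <- .icc1_ci(ms, unit, conf_level)
  } else {
    denom_s <- ms$bms + (k - 1) * ms$ems + k * (ms$jms - ms$ems) / n
    est_single <- (ms$bms - ms$ems) / denom_s
    est <- if (unit == "single") est_single
           else (ms$bms - ms$ems) / (ms$bms + (ms$jms - ms$ems) / n)
    ci <- .icc2_ci(ms, est_single, unit, conf_level)
  }
  est <- .clamp_unit(est)
  ci <- .clamp_unit(sort(ci))
  # enforce lo <= estimate <= hi after clamping
  ci[1L] <- min(ci[1L], est)
  ci[2L] <- max(ci[2L], est)
  structure(list(model = model, unit = unit, k = k, n = n,
                 estimate = est, ci95 = ci,
                 mean_squares = ms[c("bms", "wms", "jms", "ems")]),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  form <- if (x$model == "oneway") "ICC(1" else "ICC(2"
  form <- paste0(form, ",", if (x$unit == "single") 1L else x$k, ")")
  cat(sprintf("%s = %.3f, 95%% CI [%.3f, %.3f]  (n = %d targets, k = %d)\n",
              form, x$estimate, x$ci95[1L], x$ci95[2L], x$n, x$k))
  invisible(x)
}

#' Bundle the agreement statistics for a pair of measurement methods
#'
#' Convenience wrapper: Pearson correlation plus Bland-Altman limits for
#' paired measurements, optionally alongside ICC results.
#'
#' @param x Test-method measurements (degrees).
#' @param y Reference measurements (degrees).
#' @param iccs Optional list of `icc_result` objects to attach.
#' @return An object of class `agreement_report`.
#' @export
agreement_report <- function(x, y, iccs = NULL) {
  structure(list(pearson = pearson(x, y),
                 bland_altman = bland_altman(x, y),
                 icc = iccs),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("== Agreement report ==\n")
  print(x$pearson)
  print(x$bland_altman)
  for (ic in x$icc) print(ic)
  invisible(x)
}

.agreement_report_to_list <- function(rep) {
  list(
    pearson = list(r = rep$pearson$r, p_two_sided = rep$pearson$p_two_sided,
                   n = rep$pearson$n, category = rep$pearson$category),
    bland_altman = rep$bland_altman[c("mean_diff_deg", "sd_diff_deg",
                                      "upper_loa_deg", "lower_loa_deg",
                                      "half_width_deg", "n")],
    icc = lapply(rep$icc, function(ic) {
      list(model = ic$model, unit = ic$unit, k = ic$k, n = ic$n,
           estimate = ic$estimate, ci95 = ic$ci95)
    })
  )
}

#' Write an agreement report as JSON
#' @param rep An `agreement_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_agreement_report <- function(rep, path) {
  jsonlite::write_json(.agreement_report_to_list(rep), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
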
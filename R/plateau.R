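# Plateau (hold-phase) detection in a flexion-angle time series.
#
# During a trial the examiner pauses for about 3 s at each target angle;
# each pause shows up as a flat stretch of the angle trace. A rolling-window
# SD detector marks steady samples, contiguous steady runs become plateaus,
# and each plateau is summarized by the mean and SD of its samples.

# Rolling (centered, full-window) standard deviation. Values outside full
# windows are NA. The series mean is removed first to keep the cumulative
# sums well conditioned.
.roll_sd <- function(x, w) {
  n <- length(x)
  if (w > n) stop("rolling window is longer than the series", call. = FALSE)
  if (w < 2L) stop("rolling window must span at least 2 samples", call. = FALSE)
  xc <- x - mean(x)
  cs <- c(0, cumsum(xc))
  cs2 <- c(0, cumsum(xc^2))
  s <- cs[(w + 1L):(n + 1L)] - cs[1:(n - w + 1L)]
  s2 <- cs2[(w + 1L):(n + 1L)] - cs2[1:(n - w + 1L)]
  v <- pmax(0, (s2 - s^2 / w) / (w - 1L))
  out <- rep(NA_real_, n)
  half <- (w - 1L) %/% 2L
  out[(half + 1L):(half + n - w + 1L)] <- sqrt(v)
  out
}

.empty_plateau_table <- function() {
  structure(data.frame(t_start_s = numeric(0), t_end_s = numeric(0),
                       mean_deg = numeric(0), sd_deg = numeric(0),
                       n_samples = integer(0), nominal_deg = numeric(0)),
            class = c("plateau_table", "data.frame"))
}

#' Detect held (plateau) phases in an angle series
#'
#' A sample is steady when the SD of a centered rolling window around it is
#' at or below `sd_threshold_deg`. Contiguous steady runs (runs separated by
#' at most one sample are merged) of duration at least `min_duration_s`
#' become plateaus, each summarized by the mean and sample SD of its angles.
#'
#' @param series An `angle_series` with (near-)uniform sampling.
#' @param window_s Rolling window length in seconds (default 0.5).
#' @param sd_threshold_deg Steadiness threshold in degrees (default 1.5).
#' @param min_duration_s Minimum plateau duration in seconds (default 2.0,
#'   sized for the protocol's ~3 s holds).
#' @return A `plateau_table` data frame: `t_start_s`, `t_end_s`, `mean_deg`,
#'   `sd_deg`, `n_samples`, `nominal_deg` (NA until matched).
#' @export
detect_plateaus <- function(series, window_s = 0.5, sd_threshold_deg = 1.5,
                            min_duration_s = 2.0) {
  n <- nrow(series)
  if (n == 0L) stop("empty angle series", call. = FALSE)
  dt <- stats::median(diff(series$t))
  if (!is.finite(dt) || dt <= 0) {
    stop("series must have at least 2 samples at a positive rate",
         call. = FALSE)
  }
  w <- max(2L, round(window_s / dt))
  if (w %% 2L == 0L) w <- w + 1L
  steady <- .roll_sd(series$phi, w) <= sd_threshold_deg
  steady[is.na(steady)] <- FALSE

  r <- rle(steady)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  if (nrow(runs) > 1L) {
    keep <- rep(TRUE, nrow(runs))
    for (i in 2:nrow(runs)) {
      j <- max(which(keep[1:(i - 1L)]))
      if (runs$start[i] - runs$end[j] <= 2L) {  # gap of at most one sample
        runs$end[j] <- runs$end[i]
        keep[i] <- FALSE
      }
    }
    runs <- runs[keep, , drop = FALSE]
  }
  if (nrow(runs) == 0L) return(.empty_plateau_table())

  out <- lapply(seq_len(nrow(runs)), function(i) {
    sel <- runs$start[i]:runs$end[i]
    dur <- series$t[runs$end[i]] - series$t[runs$start[i]]
    if (dur < min_duration_s) return(NULL)
    phi <- series$phi[sel]
    data.frame(t_start_s = series$t[runs$start[i]],
               t_end_s = series$t[runs$end[i]],
               mean_deg = mean(phi),
               sd_deg = if (length(phi) > 1L) stats::sd(phi) else 0,
               n_samples = length(phi),
               nominal_deg = NA_real_)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(.empty_plateau_table())
  structure(out[order(out$t_start_s), , drop = FALSE],
            class = c("plateau_table", "data.frame"))
}

#' Assign plateaus to nominal target angles
#'
#' Each plateau gets the nearest nominal angle within `tol_deg`, with at
#' most one plateau per nominal: the closest wins, ties go to the earlier
#' plateau. Unassigned plateaus keep `nominal_deg = NA`.
#'
#' @param plateaus A `plateau_table`.
#' @param nominal Distinct nominal angles (degrees), default the protocol's
#'   `c(0, 45, 90, 135)`.
#' @param tol_deg Maximum |plateau mean - nominal| for a match (default 10).
#' @return The `plateau_table` with `nominal_deg` filled in.
#' @export
match_to_nominal <- function(plateaus, nominal = c(0, 45, 90, 135),
                             tol_deg = 10) {
  if (anyDuplicated(nominal)) {
    stop("nominal angles must be distinct", call. = FALSE)
  }
  plateaus$nominal_deg <- NA_real_
  if (nrow(plateaus) == 0L) return(plateaus)
  # each plateau's nearest nominal, if within tolerance
  nearest <- vapply(plateaus$mean_deg, function(m) {
    d <- abs(nominal - m)
    j <- which.min(d)
    if (d[j] <= tol_deg) nominal[j] else NA_real_
  }, numeric(1))
  # at most one plateau per nominal: closest wins, ties to the earlier start
  for (nom in nominal) {
    cand <- which(!is.na(nearest) & nearest == nom)
    if (length(cand) == 0L) next
    d <- abs(plateaus$mean_deg[cand] - nom)
    best <- cand[order(d, plateaus$t_start_s[cand])[1L]]
    plateaus$nominal_deg[best] <- nom
  }
  plateaus
}

#' Per-nominal summary of matched plateaus across trials
#'
#' @param trials List of matched `plateau_table`s (one per trial).
#' @param nominal Nominal angles to summarize, default `c(0, 45, 90, 135)`.
#' @return Data frame `nominal_deg`, `mean_deg`, `sd_deg` (sample SD across
#'   trials), `n`. A nominal with no matched plateau in any trial is kept as
#'   a missing row (`n = 0`, NA summaries).
#' @export
summarize_by_nominal <- function(trials, nominal = c(0, 45, 90, 135)) {
  rows <- lapply(nominal, function(nom) {
    vals <- unlist(lapply(trials, function(p) {
      p$mean_deg[!is.na(p$nominal_deg) & p$nominal_deg == nom]
    }))
    if (length(vals) == 0L) {
      data.frame(nominal_deg = nom, mean_deg = NA_real_, sd_deg = NA_real_,
                 n = 0L)
    } else {
      data.frame(nominal_deg = nom, mean_deg = mean(vals),
                 sd_deg = if (length(vals) > 1L) stats::sd(vals) else NA_real_,
                 n = length(vals))
    }
  })
  do.call(rbind, rows)
}

#' Write a plateau table as CSV
#' @param plateaus A `plateau_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plateau_table <- function(plateaus, path) {
  utils::write.csv(plateaus, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
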
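# Pose-stream CSV I/O.
#
# Format: header t_s,sensor_id,x_mm,y_mm,z_mm,qw,qx,qy,qz, one row per
# sample, full round-trip precision (17 significant digits). Quaternions
# are renormalized on read: silently if |norm - 1| <= 1e-6, with a warning
# up to 1e-3, and rejected beyond that (corrupt data).

.POSE_COLUMNS <- c("t_s", "sensor_id", "x_mm", "y_mm", "z_mm",
                   "qw", "qx", "qy", "qz")

#' Write a pose stream as CSV
#' @param stream A `pose_stream`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pose_stream <- function(stream, path) {
  num <- function(x) format(x, digits = 17, trim = TRUE, scientific = FALSE)
  df <- data.frame(t_s = num(stream$t),
                   sensor_id = stream$sensor_id,
                   x_mm = num(stream$position[, 1L]),
                   y_mm = num(stream$position[, 2L]),
                   z_mm = num(stream$position[, 3L]),
                   qw = num(stream$orientation[, 1L]),
                   qx = num(stream$orientation[, 2L]),
                   qy = num(stream$orientation[, 3L]),
                   qz = num(stream$orientation[, 4L]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pose stream from CSV
#'
#' Validates columns, monotone timestamps and finite values, reporting the
#' offending data line on failure. Quaternion rows are renormalized
#' (silently within 1e-6 of unit norm, with a warning within 1e-3) and
#' rejected beyond 1e-3.
#'
#' @param path CSV file with header
#'   `t_s,sensor_id,x_mm,y_mm,z_mm,qw,qx,qy,qz`.
#' @param rate_hz Nominal sampling rate to record (default: inferred from
#'   the median timestamp step, or 60 for single-sample files).
#' @return A `pose_stream`.
#' @export
read_pose_stream <- function(path, rate_hz = NULL) {
  df <- utils::read.csv(path)
  missing <- setdiff(.POSE_COLUMNS, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df$sensor_id <- as.character(df$sensor_id)
  n <- nrow(df)
  # data line i of the file is row i + 1 (header)
  line_of <- function(i) i + 1L
  num_cols <- setdiff(.POSE_COLUMNS, "sensor_id")
  for (cl in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(!is.finite(v))
    if (length(bad) > 0L) {
      stop(sprintf("%s: non-finite value in column %s at line %d", path, cl,
                   line_of(bad[1L])), call. = FALSE)
    }
    df[[cl]] <- v
  }
  if (n > 1L) {
    bad <- which(diff(df$t_s) <= 0)
    if (length(bad) > 0L) {
      stop(sprintf("%s: non-increasing timestamp at line %d", path,
                   line_of(bad[1L] + 1L)), call. = FALSE)
    }
  }
  qmat <- as.matrix(df[, c("qw", "qx", "qy", "qz")])
  qn <- sqrt(rowSums(qmat^2))
  dev <- abs(qn - 1)
  bad <- which(dev > 1e-3)
  if (length(bad) > 0L) {
    stop(sprintf("%s: quaternion norm %.4f beyond tolerance at line %d",
                 path, qn[bad[1L]], line_of(bad[1L])), call. = FALSE)
  }
  warn <- which(dev > 1e-6)
  if (length(warn) > 0L) {
    warning(sprintf("%s: %d quaternion(s) off unit norm by up to %.2e; renormalized",
                    path, length(warn), max(dev)), call. = FALSE)
  }
  if (is.null(rate_hz)) {
    rate_hz <- if (n > 1L) 1 / stats::median(diff(df$t_s)) else 60
  }
  pose_stream(df$t_s, as.matrix(df[, c("x_mm", "y_mm", "z_mm")]), qmat,
              sensor_id = if (n > 0L) df$sensor_id[1L] else "sensor",
              rate_hz = rate_hz)
}
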
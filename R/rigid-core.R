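# Rigid-body primitives: 3-vectors, scalar-first unit quaternions, timed
# poses and pose streams. Everything downstream (registration, anatomical
# frames, the simulator) is built on these.
#
# Conventions: positions in millimetres, times in seconds, angles in degrees
# at the interface (radians internally); right-handed frames throughout;
# quaternions are scalar-first (w, x, y, z) and normalized on ingest.

.DEG <- 180 / pi

deg2rad <- function(x) x / .DEG
rad2deg <- function(x) x * .DEG

#' Construct a 3-vector
#'
#' A plain numeric vector of length 3 with finiteness checks. Used for
#' positions and displacements in millimetres and for unit direction vectors.
#'
#' @param x,y,z Numeric scalars (mm, or dimensionless for unit vectors).
#' @return Numeric vector `c(x, y, z)`.
#' @export
vec3 <- function(x, y, z) {
  v <- c(as.numeric(x), as.numeric(y), as.numeric(z))
  if (length(v) != 3L || !all(is.finite(v))) {
    stop("vec3 components must be three finite numbers", call. = FALSE)
  }
  v
}

.check_vec3 <- function(v, what = "vector") {
  if (!is.numeric(v) || length(v) != 3L || !all(is.finite(v))) {
    stop(sprintf("%s must be a finite numeric vector of length 3", what),
         call. = FALSE)
  }
  as.numeric(v)
}

vnorm <- function(v) sqrt(sum(v * v))

#' Cross product of two 3-vectors
#' @param a,b Numeric length-3 vectors.
#' @return Numeric length-3 vector `a x b`.
#' @export
cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Row-wise cross product for n x 3 matrices.
cross_rows <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

normalize_rows <- function(m) {
  n <- sqrt(rowSums(m * m))
  m / n
}

#' Construct a unit quaternion (scalar-first)
#'
#' The input is normalized; construction fails for a (near-)zero quaternion.
#'
#' @param w,x,y,z Numeric components, scalar part first.
#' @return Numeric vector `c(w, x, y, z)` with unit norm.
#' @export
unit_quaternion <- function(w, x, y, z) {
  q <- c(as.numeric(w), as.numeric(x), as.numeric(y), as.numeric(z))
  if (!all(is.finite(q))) {
    stop("quaternion components must be finite", call. = FALSE)
  }
  n <- vnorm(q)
  if (n < 1e-12) stop("cannot normalize a zero quaternion", call. = FALSE)
  q / n
}

.check_unit_quaternion <- function(q, tol = 1e-9) {
  if (!is.numeric(q) || length(q) != 4L || !all(is.finite(q))) {
    stop("quaternion must be a finite numeric vector of length 4",
         call. = FALSE)
  }
  if (abs(vnorm(q) - 1) > tol) {
    stop(sprintf("quaternion norm deviates from 1 by more than %g", tol),
         call. = FALSE)
  }
  as.numeric(q)
}

#' Quaternion from an axis-angle rotation
#'
#' @param axis Rotation axis (any nonzero length-3 vector; normalized).
#' @param angle_deg Rotation angle in degrees (right-hand rule).
#' @return Scalar-first unit quaternion.
#' @export
quat_from_axis_angle <- function(axis, angle_deg) {
  axis <- .check_vec3(axis, "axis")
  n <- vnorm(axis)
  if (n < 1e-12) stop("rotation axis must be nonzero", call. = FALSE)
  half <- deg2rad(angle_deg) / 2
  c(cos(half), sin(half) * axis / n)
}

#' Hamilton product of two scalar-first quaternions
#' @param a,b Scalar-first quaternions.
#' @return Scalar-first quaternion `a %*% b` (apply `b`'s rotation first).
#' @export
quat_multiply <- function(a, b) {
  w1 <- a[1L]; v1 <- a[2:4]
  w2 <- b[1L]; v2 <- b[2:4]
  c(w1 * w2 - sum(v1 * v2), w1 * v2 + w2 * v1 + cross3(v1, v2))
}

#' Rotation matrix of a unit quaternion
#' @param q Scalar-first unit quaternion.
#' @return 3 x 3 rotation matrix.
#' @export
quat_to_matrix <- function(q) {
  q <- .check_unit_quaternion(q, tol = 1e-6)
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(
    1 - 2 * (y * y + z * z), 2 * (x * y - w * z),     2 * (x * z + w * y),
    2 * (x * y + w * z),     1 - 2 * (x * x + z * z), 2 * (y * z - w * x),
    2 * (x * z - w * y),     2 * (y * z + w * x),     1 - 2 * (x * x + y * y)
  ), nrow = 3L, byrow = TRUE)
}

# Rotate rows of V (n x 3) by quaternions Q (n x 4 or length 4), vectorized:
# p' = p + w*t + v x t with t = 2 (v x p).
quat_rotate_rows <- function(Q, V) {
  if (is.null(dim(Q))) Q <- matrix(Q, nrow = nrow(V), ncol = 4L, byrow = TRUE)
  qv <- Q[, 2:4, drop = FALSE]
  t2 <- 2 * cross_rows(qv, V)
  V + Q[, 1L] * t2 + cross_rows(qv, t2)
}

#' Construct a timed rigid pose
#'
#' One sensor sample: a timestamp, a position in the transmitter (world)
#' frame, and an orientation quaternion mapping sensor-local coordinates to
#' world coordinates. The quaternion is normalized on ingest.
#'
#' @param t Time in seconds, finite and non-negative.
#' @param position Length-3 position (mm).
#' @param orientation Scalar-first quaternion (normalized on ingest).
#' @return An object of class `rigid_pose`.
#' @export
rigid_pose <- function(t, position, orientation) {
  t <- as.numeric(t)
  if (length(t) != 1L || !is.finite(t) || t < 0) {
    stop("pose time must be a finite non-negative scalar", call. = FALSE)
  }
  position <- .check_vec3(position, "position")
  orientation <- unit_quaternion(orientation[1L], orientation[2L],
                                 orientation[3L], orientation[4L])
  structure(list(t = t, position = position, orientation = orientation),
            class = "rigid_pose")
}

#' Construct a pose stream for one sensor
#'
#' @param t Strictly increasing timestamps (s).
#' @param position n x 3 matrix of positions (mm).
#' @param orientation n x 4 matrix of scalar-first quaternions (rows
#'   normalized on ingest).
#' @param sensor_id Identifier string.
#' @param rate_hz Nominal sampling rate (default 60, the tracker's rate).
#' @return An object of class `pose_stream`.
#' @export
pose_stream <- function(t, position, orientation, sensor_id = "sensor",
                        rate_hz = 60) {
  t <- as.numeric(t)
  position <- matrix(as.numeric(position), ncol = 3L)
  orientation <- matrix(as.numeric(orientation), ncol = 4L)
  n <- length(t)
  if (nrow(position) != n || nrow(orientation) != n) {
    stop("timestamps, positions and orientations must have equal length",
         call. = FALSE)
  }
  if (n > 0L) {
    if (!all(is.finite(t)) || any(diff(t) <= 0)) {
      stop("timestamps must be finite and strictly increasing", call. = FALSE)
    }
    if (!all(is.finite(position)) || !all(is.finite(orientation))) {
      stop("pose stream contains non-finite values", call. = FALSE)
    }
    qn <- sqrt(rowSums(orientation^2))
    if (any(qn < 1e-12)) stop("zero quaternion in pose stream", call. = FALSE)
    orientation <- orientation / qn
  }
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0) {
    stop("rate_hz must be a positive scalar", call. = FALSE)
  }
  structure(list(t = t, position = position, orientation = orientation,
                 sensor_id = as.character(sensor_id),
                 rate_hz = as.numeric(rate_hz)),
            class = "pose_stream")
}

#' @export
length.pose_stream <- function(x) length(x$t)

#' Extract one sample of a pose stream as a rigid pose
#' @param stream A `pose_stream`.
#' @param i Sample index.
#' @return A `rigid_pose`.
#' @export
pose_at <- function(stream, i) {
  rigid_pose(stream$t[i], stream$position[i, ], stream$orientation[i, ])
}

#' @export
print.pose_stream <- function(x, ...) {
  cat(sprintf("<pose_stream '%s': %d samples @ %g Hz", x$sensor_id,
              length(x$t), x$rate_hz))
  if (length(x$t) > 0L) {
    cat(sprintf(", t = [%.3f, %.3f] s", x$t[1L], x$t[length(x$t)]))
  }
  cat(">\n")
  invisible(x)
}

#' Map a sensor-local point to world coordinates
#'
#' `R(q) . local + position` for the pose's orientation quaternion `q`.
#'
#' @param pose A `rigid_pose` (or list with `position`/`orientation`).
#' @param local Length-3 point in the sensor frame (mm).
#' @return Length-3 world point (mm).
#' @export
transform_point <- function(pose, local) {
  local <- .check_vec3(local, "local point")
  q <- .check_unit_quaternion(pose$orientation, tol = 1e-6)
  drop(quat_rotate_rows(q, matrix(local, nrow = 1L))) + pose$position
}

#' Map a world point into sensor-local coordinates
#'
#' Exact inverse of [transform_point()]: `R(q)^T (global - position)`.
#'
#' @param pose A `rigid_pose`.
#' @param global Length-3 world point (mm).
#' @return Length-3 point in the sensor frame (mm).
#' @export
inverse_transform_point <- function(pose, global) {
  global <- .check_vec3(global, "global point")
  q <- .check_unit_quaternion(pose$orientation, tol = 1e-6)
  qc <- c(q[1L], -q[2:4])
  drop(quat_rotate_rows(qc, matrix(global - pose$position, nrow = 1L)))
}

#' Angle between two unit vectors, in degrees
#'
#' `acos` of the dot product, clamped to \[-1, 1\] so that tiny rounding
#' excursions never raise a domain error. Result lies in \[0, 180\].
#'
#' @param u,v Unit vectors (norm within 1e-6 of 1).
#' @return Angle in degrees.
#' @export
angle_between_unit_vectors <- function(u, v) {
  u <- .check_vec3(u, "u"); v <- .check_vec3(v, "v")
  if (abs(vnorm(u) - 1) > 1e-6 || abs(vnorm(v) - 1) > 1e-6) {
    stop("angle_between_unit_vectors requires unit vectors (|norm - 1| <= 1e-6)",
         call. = FALSE)
  }
  d <- sum(u * v)
  rad2deg(acos(min(1, max(-1, d))))
}
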
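# Anatomical frames and the flexion angle.
#
# Upper-arm frame: origin at p_lm2 (midpoint of the epicondyles), uz along
# the humeral shaft toward the greater tubercle, uy normal to the plane of
# the lateral epicondyle and the shaft, ux completing the right-handed
# triple. Forearm frame: origin at p_ru2 (midpoint of the styloids), fz from
# the wrist toward the elbow, fy from the radial styloid direction crossed
# with fz. Flexion angle: phi = acos(uy . fy), so a straight arm reads 0 deg
# and deep flexion about 135 deg.

# Two landmark-difference vectors span a triangle; below this area the
# frame construction is numerically meaningless.
.MIN_TRIANGLE_AREA_MM2 <- 1

#' Midpoint of two points
#' @param a,b Length-3 points (mm).
#' @return Component-wise mean.
#' @export
midpoint <- function(a, b) {
  (.check_vec3(a, "a") + .check_vec3(b, "b")) / 2
}

#' Construct an anatomical frame
#'
#' Validates orthonormality and right-handedness (`ux x uy = uz`) to 1e-9.
#'
#' @param origin Length-3 origin (mm).
#' @param ux,uy,uz Unit axis vectors.
#' @return An object of class `anatomical_frame`.
#' @export
anatomical_frame <- function(origin, ux, uy, uz) {
  origin <- .check_vec3(origin, "origin")
  ux <- .check_vec3(ux, "ux"); uy <- .check_vec3(uy, "uy")
  uz <- .check_vec3(uz, "uz")
  tol <- 1e-9
  if (abs(vnorm(ux) - 1) > tol || abs(vnorm(uy) - 1) > tol ||
      abs(vnorm(uz) - 1) > tol) {
    stop("frame axes must be unit vectors", call. = FALSE)
  }
  if (abs(sum(ux * uy)) > tol || abs(sum(uy * uz)) > tol ||
      abs(sum(ux * uz)) > tol) {
    stop("frame axes must be mutually orthogonal", call. = FALSE)
  }
  if (vnorm(cross3(ux, uy) - uz) > 1e-8) {
    stop("frame must be right-handed (ux x uy = uz)", call. = FALSE)
  }
  structure(list(origin = origin, ux = ux, uy = uy, uz = uz),
            class = "anatomical_frame")
}

#' @export
print.anatomical_frame <- function(x, ...) {
  cat("<anatomical_frame>\n")
  cat(sprintf("  origin (%.3f, %.3f, %.3f) mm\n",
              x$origin[1L], x$origin[2L], x$origin[3L]))
  for (ax in c("ux", "uy", "uz")) {
    v <- x[[ax]]
    cat(sprintf("  %s = (%+.6f, %+.6f, %+.6f)\n", ax, v[1L], v[2L], v[3L]))
  }
  invisible(x)
}

.triangle_area <- function(a, b, c) vnorm(cross3(b - a, c - a)) / 2

#' Upper-arm (humeral) anatomical frame from three landmarks
#'
#' Origin at `p_lm2 = midpoint(p_m, p_l)`; `uz` toward the greater tubercle;
#' `uy = normalize((p_l - p_lm2) x uz)`; `ux = uy x uz`.
#'
#' @param p_g Greater tubercle of the humerus (mm).
#' @param p_m,p_l Medial and lateral epicondyles (mm).
#' @return An `anatomical_frame`.
#' @export
humerus_frame <- function(p_g, p_m, p_l) {
  p_g <- .check_vec3(p_g, "p_g"); p_m <- .check_vec3(p_m, "p_m")
  p_l <- .check_vec3(p_l, "p_l")
  if (.triangle_area(p_g, p_m, p_l) < .MIN_TRIANGLE_AREA_MM2) {
    stop("degenerate humeral geometry: landmarks are (near-)collinear",
         call. = FALSE)
  }
  p_lm2 <- midpoint(p_m, p_l)
  uz <- p_g - p_lm2
  uz <- uz / vnorm(uz)
  uy <- cross3(p_l - p_lm2, uz)
  uy <- uy / vnorm(uy)
  ux <- cross3(uy, uz)
  anatomical_frame(p_lm2, ux, uy, uz)
}

#' Forearm anatomical frame from the elbow midpoint and wrist landmarks
#'
#' Origin at `p_ru2 = midpoint(p_u, p_r)`; `fz` toward the elbow midpoint
#' `p_lm2`; `fy = normalize((p_r - p_ru2) x fz)`; `fx = fy x fz`.
#'
#' @param p_lm2 Midpoint of the epicondyles (mm).
#' @param p_r,p_u Radial and ulnar styloid processes (mm).
#' @return An `anatomical_frame`.
#' @export
forearm_frame <- function(p_lm2, p_r, p_u) {
  p_lm2 <- .check_vec3(p_lm2, "p_lm2"); p_r <- .check_vec3(p_r, "p_r")
  p_u <- .check_vec3(p_u, "p_u")
  if (.triangle_area(p_lm2, p_r, p_u) < .MIN_TRIANGLE_AREA_MM2) {
    stop("degenerate forearm geometry: landmarks are (near-)collinear",
         call. = FALSE)
  }
  p_ru2 <- midpoint(p_u, p_r)
  fz <- p_lm2 - p_ru2
  fz <- fz / vnorm(fz)
  fy <- cross3(p_r - p_ru2, fz)
  fy <- fy / vnorm(fy)
  fx <- cross3(fy, fz)
  anatomical_frame(p_ru2, fx, fy, fz)
}

#' Elbow flexion angle from the two anatomical frames
#'
#' `phi = acos(uy . fy)` in degrees, in \[0, 180\]. Hyperextension is not
#' signed: the acos definition folds it onto small positive angles.
#'
#' @param humerus,forearm `anatomical_frame` objects.
#' @return Flexion angle in degrees.
#' @export
flexion_angle <- function(humerus, forearm) {
  angle_between_unit_vectors(humerus$uy, forearm$uy)
}

#' Construct an angle time series
#' @param t Timestamps (s).
#' @param phi Flexion angles (degrees, in \[0, 180\]).
#' @return Data frame of class `angle_series` with columns `t`, `phi`.
#' @export
angle_series <- function(t, phi) {
  t <- as.numeric(t); phi <- as.numeric(phi)
  if (length(t) != length(phi)) {
    stop("t and phi must have equal length", call. = FALSE)
  }
  if (length(phi) > 0L &&
      (any(!is.finite(phi)) || any(phi < -1e-9) || any(phi > 180 + 1e-9))) {
    stop("phi must be finite and within [0, 180] degrees", call. = FALSE)
  }
  structure(data.frame(t = t, phi = phi),
            class = c("angle_series", "data.frame"))
}

#' Flexion-angle time series from two sensor streams and a registry
#'
#' Pairs each humerus sample with the nearest forearm sample (gap at most
#' half a sample period), reconstructs the five landmarks, builds both
#' anatomical frames and evaluates the flexion angle per sample. Samples
#' with degenerate landmark geometry are excluded and reported via a
#' warning; their indices are attached as attribute `"excluded"`.
#'
#' @param humerus_stream,forearm_stream `pose_stream` objects.
#' @param reg A `landmark_registry`.
#' @return An `angle_series`.
#' @export
angle_timeseries <- function(humerus_stream, forearm_stream, reg) {
  if (length(humerus_stream) == 0L || length(forearm_stream) == 0L) {
    return(angle_series(numeric(0), numeric(0)))
  }
  idx <- .align_to(humerus_stream$t, forearm_stream, "forearm stream")
  hp <- humerus_stream$position
  hq <- humerus_stream$orientation
  fp <- forearm_stream$position[idx, , drop = FALSE]
  fq <- forearm_stream$orientation[idx, , drop = FALSE]
  lm <- .reconstruct_landmarks_rows(reg, hp, hq, fp, fq)

  p_lm2 <- (lm$p_m + lm$p_l) / 2
  p_ru2 <- (lm$p_u + lm$p_r) / 2

  uz <- lm$p_g - p_lm2
  uy_raw <- cross_rows(lm$p_l - p_lm2, uz)
  fz <- p_lm2 - p_ru2
  fy_raw <- cross_rows(lm$p_r - p_ru2, fz)

  # degenerate samples: either triangle collapses below the area threshold
  hum_area <- sqrt(rowSums(cross_rows(lm$p_m - lm$p_g, lm$p_l - lm$p_g)^2)) / 2
  fore_area <- sqrt(rowSums(cross_rows(lm$p_r - p_lm2, lm$p_u - p_lm2)^2)) / 2
  ok <- hum_area >= .MIN_TRIANGLE_AREA_MM2 & fore_area >= .MIN_TRIANGLE_AREA_MM2

  uzn <- sqrt(rowSums(uz^2)); fzn <- sqrt(rowSums(fz^2))
  ok <- ok & uzn > 1e-9 & fzn > 1e-9

  uy <- normalize_rows(uy_raw)
  fy <- normalize_rows(fy_raw)
  d <- rowSums(uy * fy)
  phi <- rad2deg(acos(pmin(1, pmax(-1, d))))

  if (!all(ok)) {
    warning(sprintf("%d sample(s) with degenerate landmark geometry excluded",
                    sum(!ok)), call. = FALSE)
  }
  out <- angle_series(humerus_stream$t[ok], phi[ok])
  attr(out, "excluded") <- which(!ok)
  out
}

#' Write an angle series as CSV (`t_s`, `phi_deg`)
#' @param series An `angle_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_angle_series <- function(series, path) {
  df <- data.frame(t_s = format(series$t, digits = 17, trim = TRUE,
                                scientific = FALSE),
                   phi_deg = format(series$phi, digits = 17, trim = TRUE,
                                    scientific = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an angle series from CSV written by [write_angle_series()]
#' @param path Input path.
#' @return An `angle_series`.
#' @export
read_angle_series <- function(path) {
  df <- utils::read.csv(path)
  need <- c("t_s", "phi_deg")
  if (!all(need %in% names(df))) {
    stop("angle series CSV must have columns t_s, phi_deg", call. = FALSE)
  }
  angle_series(df$t_s, df$phi_deg)
}
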
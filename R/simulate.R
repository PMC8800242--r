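# Synthetic-trial generator standing in for the electromagnetic tracker and
# the radiographic reference.
#
# Geometry is a simplified planar hinge: the humerus is fixed with the
# epicondylar axis along world x and the shaft along world z; the forearm
# rotates about that axis through a ramp-and-hold trajectory. Supination is
# locked, so all five landmarks are rigid with their host sensors. Sensor
# noise follows the manufacturer's stated root-mean-square accuracy
# (position RMS of the 3-D error vector; orientation RMS rotation angle
# about a uniformly random axis). Examiner hold placement, stylus
# digitization error, an in-vivo soft-tissue artifact that grows with
# flexion, and a noisy radiographic reading are all modeled explicitly.

#' Simulation configuration
#'
#' Defaults encode the study conditions: 60 Hz sampling, 0.76 mm / 0.15 deg
#' RMS sensor noise, ~3 s holds with 1 s ramps, 1 deg examiner hold
#' variability, and segment lengths of an adult arm.
#'
#' @param humerus_length Humerus length, mm.
#' @param forearm_length Forearm length (elbow to wrist midpoint), mm.
#' @param epicondylar_halfwidth Half the inter-epicondylar distance, mm.
#' @param wrist_halfwidth Half the inter-styloid distance, mm.
#' @param rate_hz Sampling rate of the tracker.
#' @param pos_noise_rms RMS of the 3-D sensor position error vector, mm.
#' @param ori_noise_rms RMS sensor orientation error angle, degrees.
#' @param hold_s Duration of each held target angle, seconds.
#' @param ramp_s Duration of each ramp between targets, seconds.
#' @param hold_sd_deg SD of the examiner's placement around each target,
#'   degrees.
#' @param digitization_noise_mm RMS of the stylus-tip error vector during
#'   landmark digitization, mm.
#' @param artifact_gain Soft-tissue artifact scale (in-vivo only): the
#'   artifact rotation SD is `artifact_gain * true_flexion` degrees.
#' @param xray_noise_sd_deg SD of the simulated radiographic reading around
#'   the true held angle, degrees.
#' @param seed Integer seed; all randomness flows through it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(humerus_length = 300, forearm_length = 250,
                       epicondylar_halfwidth = 30, wrist_halfwidth = 25,
                       rate_hz = 60, pos_noise_rms = 0.76,
                       ori_noise_rms = 0.15, hold_s = 3.0, ramp_s = 1.0,
                       hold_sd_deg = 1.0, digitization_noise_mm = 0.76,
                       artifact_gain = 0.08, xray_noise_sd_deg = 1.0,
                       seed = 1L) {
  cfg <- list(humerus_length = humerus_length,
              forearm_length = forearm_length,
              epicondylar_halfwidth = epicondylar_halfwidth,
              wrist_halfwidth = wrist_halfwidth,
              rate_hz = rate_hz, pos_noise_rms = pos_noise_rms,
              ori_noise_rms = ori_noise_rms, hold_s = hold_s,
              ramp_s = ramp_s, hold_sd_deg = hold_sd_deg,
              digitization_noise_mm = digitization_noise_mm,
              artifact_gain = artifact_gain,
              xray_noise_sd_deg = xray_noise_sd_deg,
              seed = as.integer(seed))
  for (nm in c("humerus_length", "forearm_length", "epicondylar_halfwidth",
               "wrist_halfwidth", "rate_hz", "hold_s", "ramp_s")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(nm, " must be a positive scalar", call. = FALSE)
    }
  }
  for (nm in c("pos_noise_rms", "ori_noise_rms", "hold_sd_deg",
               "digitization_noise_mm", "artifact_gain",
               "xray_noise_sd_deg")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop(nm, " must be a non-negative scalar", call. = FALSE)
    }
  }
  if (is.na(cfg$seed)) stop("seed must be an integer", call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (nm in names(unclass(x))) cat(sprintf("  %-22s %s\n", nm, x[[nm]]))
  invisible(x)
}

#' Write / read a simulation configuration as YAML
#' @param cfg A `sim_config`.
#' @param path File path.
#' @return `path` (write) or a `sim_config` (read).
#' @export
write_sim_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  do.call(sim_config, yaml::read_yaml(path))
}

# Deterministic sub-seed derivation: one global seed, per-trial offsets.
.sub_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(index)) %% 2147483647)
}

# True landmark positions (world, reference configuration phi = 0) and the
# reference poses of the two bone sensors.
.model_geometry <- function(cfg) {
  list(
    landmarks = list(
      p_g = c(0, 0, cfg$humerus_length),
      p_m = c(-cfg$epicondylar_halfwidth, 0, 0),
      p_l = c(cfg$epicondylar_halfwidth, 0, 0),
      p_r = c(cfg$wrist_halfwidth, 0, -cfg$forearm_length),
      p_u = c(-cfg$wrist_halfwidth, 0, -cfg$forearm_length)
    ),
    humerus_ref = list(position = c(10, 20, 150),
                       orientation = quat_from_axis_angle(c(1, 2, 3), 25)),
    forearm_ref = list(position = c(0, 8, -120),
                       orientation = quat_from_axis_angle(c(3, -1, 2), 40))
  )
}

# Ramp-and-hold interpolation: hold `values[j]` for hold_s, linear ramp of
# ramp_s to the next value. Returns t and the per-sample value series.
.ramp_hold_series <- function(values, cfg) {
  m <- length(values)
  total <- m * cfg$hold_s + (m - 1) * cfg$ramp_s
  t <- seq(0, total, by = 1 / cfg$rate_hz)
  knot_t <- numeric(0)
  knot_v <- numeric(0)
  cur <- 0
  for (j in seq_len(m)) {
    knot_t <- c(knot_t, cur, cur + cfg$hold_s)
    knot_v <- c(knot_v, values[j], values[j])
    cur <- cur + cfg$hold_s + cfg$ramp_s
  }
  v <- stats::approx(knot_t, knot_v, xout = t, rule = 2)$y
  list(t = t, v = v)
}

# Isotropic Gaussian position noise with a prescribed RMS of the 3-D error
# vector: per-axis sigma = rms / sqrt(3).
.position_noise <- function(n, rms) {
  matrix(stats::rnorm(3L * n, 0, rms / sqrt(3)), ncol = 3L)
}

# Small-rotation noise: angle |N(0, rms^2)| degrees about a uniformly random
# axis; returned as n x 4 scalar-first quaternions.
.orientation_noise <- function(n, rms_deg) {
  if (rms_deg == 0) {
    return(cbind(rep(1, n), 0, 0, 0))
  }
  ax <- matrix(stats::rnorm(3L * n), ncol = 3L)
  ax <- normalize_rows(ax)
  ang <- abs(stats::rnorm(n, 0, rms_deg))
  half <- deg2rad(ang) / 2
  cbind(cos(half), sin(half) * ax)
}

# Row-wise Hamilton product of n x 4 quaternion matrices (a applied after b).
.quat_multiply_rows <- function(a, b) {
  w1 <- a[, 1L]; v1 <- a[, 2:4, drop = FALSE]
  w2 <- b[, 1L]; v2 <- b[, 2:4, drop = FALSE]
  cbind(w1 * w2 - rowSums(v1 * v2),
        w1 * v2 + w2 * v1 + cross_rows(v1, v2))
}

# Hinge rotation quaternions about world x for per-sample angles (degrees).
.hinge_quats <- function(phi_deg) {
  half <- deg2rad(phi_deg) / 2
  cbind(cos(half), sin(half), 0, 0)
}

# Noisy pose stream around given true positions/orientations.
.noisy_stream <- function(t, pos, quat, cfg, sensor_id) {
  n <- length(t)
  pos <- pos + .position_noise(n, cfg$pos_noise_rms)
  quat <- .quat_multiply_rows(.orientation_noise(n, cfg$ori_noise_rms), quat)
  pose_stream(t, pos, quat, sensor_id = sensor_id, rate_hz = cfg$rate_hz)
}

# Digitize the full registry from simulated 1-s stylus windows against the
# (noisy) fixed sensors at the reference configuration.
.digitize_registry <- function(cfg, geom) {
  n_dig <- max(1L, round(cfg$rate_hz))
  t <- seq_len(n_dig) / cfg$rate_hz
  entries <- list()
  for (id in LANDMARK_IDS) {
    host_ref <- if (identical(unname(LANDMARK_HOSTS[[id]]), "humerus")) {
      geom$humerus_ref
    } else {
      geom$forearm_ref
    }
    host <- .noisy_stream(t,
                          matrix(host_ref$position, n_dig, 3L, byrow = TRUE),
                          matrix(host_ref$orientation, n_dig, 4L, byrow = TRUE),
                          cfg, paste0("host_", id))
    tip <- matrix(geom$landmarks[[id]], n_dig, 3L, byrow = TRUE) +
      .position_noise(n_dig, cfg$digitization_noise_mm)
    stylus <- pose_stream(t, tip, matrix(c(1, 0, 0, 0), n_dig, 4L,
                                         byrow = TRUE),
                          sensor_id = "stylus", rate_hz = cfg$rate_hz)
    entries[[id]] <- digitize_landmark(stylus, host, id)
  }
  landmark_registry(entries)
}

# Shared trial assembly: truth trajectory phi(t), forearm sensor driven by
# phi(t) + artifact(t), both sensors perturbed by measurement noise.
.assemble_trial <- function(cfg, phi_truth, artifact, ts) {
  geom <- .model_geometry(cfg)
  n <- length(ts)
  registry <- .digitize_registry(cfg, geom)

  hum <- .noisy_stream(ts,
                       matrix(geom$humerus_ref$position, n, 3L, byrow = TRUE),
                       matrix(geom$humerus_ref$orientation, n, 4L,
                              byrow = TRUE),
                       cfg, "humerus")

  hinge <- .hinge_quats(phi_truth + artifact)
  fpos <- quat_rotate_rows(hinge,
                           matrix(geom$forearm_ref$position, n, 3L,
                                  byrow = TRUE))
  fquat <- .quat_multiply_rows(hinge,
                               matrix(geom$forearm_ref$orientation, n, 4L,
                                      byrow = TRUE))
  fore <- .noisy_stream(ts, fpos, fquat, cfg, "forearm")

  list(humerus_stream = hum, forearm_stream = fore, registry = registry,
       truth = angle_series(ts, phi_truth))
}

#' Simulate one model-bone trial
#'
#' The humerus is fixed; an examiner flexes the forearm through a
#' ramp-and-hold trajectory pausing at each nominal angle. Actual hold
#' placement is `nominal + N(0, hold_sd_deg^2)` (clamped to \[0, 180\]).
#' Sensor poses carry the configured position/orientation noise, and the
#' landmark registry is digitized with stylus noise. Fully deterministic
#' given `cfg$seed`.
#'
#' @param cfg A `sim_config`.
#' @param nominal Target angles visited, default `c(0, 45, 90, 135)`.
#' @return An object of class `simulated_trial`: `humerus_stream`,
#'   `forearm_stream`, `registry`, `truth` (noiseless `angle_series`),
#'   `hold_targets`, `nominal`, `xray_readings` (NULL here), `config`.
#' @export
simulate_model_bone_trial <- function(cfg, nominal = c(0, 45, 90, 135)) {
  stopifnot(inherits(cfg, "sim_config"))
  if (length(nominal) < 1L || any(!is.finite(nominal)) ||
      any(nominal < 0 | nominal > 180)) {
    stop("nominal angles must lie in [0, 180] degrees", call. = FALSE)
  }
  set.seed(cfg$seed)
  targets <- pmin(180, pmax(0, nominal + stats::rnorm(length(nominal), 0,
                                                      cfg$hold_sd_deg)))
  traj <- .ramp_hold_series(targets, cfg)
  trial <- .assemble_trial(cfg, traj$v, artifact = 0, ts = traj$t)
  trial$hold_targets <- targets
  trial$nominal <- nominal
  trial$xray_readings <- NULL
  trial$config <- cfg
  structure(trial, class = "simulated_trial")
}

#' Simulate one in-vivo trial with soft-tissue artifact and radiographs
#'
#' The participant moves to maximum extension, holds, then to maximum
#' flexion and holds. The forearm sensor is additionally perturbed by a
#' per-hold soft-tissue artifact rotation with SD
#' `artifact_gain * true_angle` degrees (brace displacement from biceps
#' contraction), so measurement error grows with flexion. A paired
#' radiographic reading per extreme is the true held angle plus
#' `N(0, xray_noise_sd_deg^2)`.
#'
#' @param cfg A `sim_config`.
#' @param extremes `c(extension_true, flexion_true)` in degrees, with
#'   `0 <= extension_true < flexion_true <= 180`.
#' @return A `simulated_trial`; `xray_readings` holds the two paired
#'   radiographic angles (extension, flexion).
#' @export
simulate_in_vivo_trial <- function(cfg, extremes) {
  stopifnot(inherits(cfg, "sim_config"))
  if (length(extremes) != 2L || any(!is.finite(extremes)) ||
      extremes[1L] < 0 || extremes[2L] > 180 ||
      extremes[1L] >= extremes[2L]) {
    stop("extremes must satisfy 0 <= extension < flexion <= 180",
         call. = FALSE)
  }
  set.seed(cfg$seed)
  targets <- pmin(180, pmax(0, extremes + stats::rnorm(2L, 0,
                                                       cfg$hold_sd_deg)))
  artifact_hold <- stats::rnorm(2L, 0, cfg$artifact_gain * targets)
  traj <- .ramp_hold_series(targets, cfg)
  art <- .ramp_hold_series(artifact_hold, cfg)
  trial <- .assemble_trial(cfg, traj$v, artifact = art$v, ts = traj$t)
  trial$hold_targets <- targets
  trial$nominal <- extremes
  trial$xray_readings <- targets + stats::rnorm(2L, 0, cfg$xray_noise_sd_deg)
  trial$config <- cfg
  structure(trial, class = "simulated_trial")
}

#' @export
print.simulated_trial <- function(x, ...) {
  cat(sprintf("<simulated_trial: %d samples, holds at %s deg%s>\n",
              length(x$truth$t),
              paste(sprintf("%.1f", x$hold_targets), collapse = ", "),
              if (is.null(x$xray_readings)) "" else ", with radiographs"))
  invisible(x)
}
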
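# Shared fixtures: random rotations/poses and an independent rotation
# oracle (Rodrigues axis-angle formula), used to check the quaternion path.

rodrigues_matrix <- function(axis, angle_deg) {
  axis <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

rand_unit_vec <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

rand_quat <- function() {
  quat_from_axis_angle(rand_unit_vec(), runif(1, -180, 180))
}

rand_pose <- function(t = 0) {
  rigid_pose(t, rnorm(3, 0, 100), rand_quat())
}

# Synthetic landmark set of a hinged arm at a given flexion angle:
# humerus fixed (shaft along +z, epicondylar axis along x), forearm
# landmarks rotated about the x axis through the elbow midpoint.
landmarks_at_flexion <- function(phi_deg, humerus_length = 300,
                                 forearm_length = 250, ehw = 30, whw = 25) {
  R <- rodrigues_matrix(c(1, 0, 0), phi_deg)
  p_ru2 <- drop(R %*% c(0, 0, -forearm_length))
  list(p_g = c(0, 0, humerus_length),
       p_m = c(-ehw, 0, 0),
       p_l = c(ehw, 0, 0),
       p_r = p_ru2 + drop(R %*% c(whw, 0, 0)),
       p_u = p_ru2 - drop(R %*% c(whw, 0, 0)))
}

# Constant-pose stream helper.
const_stream <- function(n, position, orientation, rate_hz = 60,
                         sensor_id = "sensor", t0 = 0) {
  pose_stream(t0 + seq_len(n) / rate_hz,
              matrix(position, n, 3, byrow = TRUE),
              matrix(orientation, n, 4, byrow = TRUE),
              sensor_id = sensor_id, rate_hz = rate_hz)
}

IDENTITY_QUAT <- c(1, 0, 0, 0)
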
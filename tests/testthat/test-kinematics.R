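# Anatomical frames and flexion-angle extraction.

test_that("midpoint is the component-wise mean", {
  expect_equal(midpoint(c(0, 0, 0), c(2, 0, 0)), c(1, 0, 0))
  a <- c(1.5, -2, 7)
  expect_equal(midpoint(a, a), a)
  expect_equal(midpoint(c(-30, 0, 0), c(30, 0, 0)), c(0, 0, 0))
})

test_that("humerus_frame produces the documented axes", {
  fr <- humerus_frame(p_g = c(0, 0, 300), p_m = c(-30, 0, 0),
                      p_l = c(30, 0, 0))
  expect_equal(fr$origin, c(0, 0, 0))
  expect_equal(fr$uz, c(0, 0, 1))
  expect_equal(fr$uy, c(0, -1, 0))
  expect_equal(fr$ux, c(-1, 0, 0))

  # directions are scale-invariant
  fr2 <- humerus_frame(c(0, 0, 600), c(-60, 0, 0), c(60, 0, 0))
  expect_equal(fr2$ux, fr$ux)
  expect_equal(fr2$uy, fr$uy)
  expect_equal(fr2$uz, fr$uz)
})

test_that("forearm_frame produces the documented axes and rejects degeneracy", {
  fr <- forearm_frame(p_lm2 = c(0, 0, 250), p_r = c(25, 0, 0),
                      p_u = c(-25, 0, 0))
  expect_equal(fr$origin, c(0, 0, 0))
  expect_equal(fr$uz, c(0, 0, 1))
  expect_equal(fr$uy, c(0, -1, 0))
  expect_equal(fr$ux, c(-1, 0, 0))

  expect_error(forearm_frame(c(0, 0, 250), c(25, 0, 0), c(25, 0, 0)),
               "degenerate")
  expect_error(humerus_frame(c(0, 0, 300), c(0, 0, 100), c(0, 0, 200)),
               "degenerate")
})

test_that("frames are orthonormal, right-handed and rotate with the bones", {
  set.seed(13)
  for (i in 1:30) {
    p_g <- rnorm(3, c(0, 0, 300), 40)
    p_m <- rnorm(3, c(-30, 0, 0), 10)
    p_l <- rnorm(3, c(30, 0, 0), 10)
    fr <- humerus_frame(p_g, p_m, p_l)
    # constructor asserts orthonormality/handedness at 1e-9; check explicitly
    G <- rbind(fr$ux, fr$uy, fr$uz)
    expect_equal(G %*% t(G), diag(3), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(cross3(fr$ux, fr$uy), fr$uz, tolerance = 1e-9)

    # applying a rigid motion to the landmarks rotates the axes by R
    R <- rodrigues_matrix(rand_unit_vec(), runif(1, -180, 180))
    tr <- rnorm(3, 0, 100)
    fr_m <- humerus_frame(drop(R %*% p_g) + tr, drop(R %*% p_m) + tr,
                          drop(R %*% p_l) + tr)
    expect_equal(fr_m$ux, drop(R %*% fr$ux), tolerance = 1e-9)
    expect_equal(fr_m$uy, drop(R %*% fr$uy), tolerance = 1e-9)
    expect_equal(fr_m$uz, drop(R %*% fr$uz), tolerance = 1e-9)
  }
})

test_that("flexion angle tracks hinge rotation of the forearm landmarks", {
  straight <- landmarks_at_flexion(0)
  hf <- humerus_frame(straight$p_g, straight$p_m, straight$p_l)
  p_lm2 <- midpoint(straight$p_m, straight$p_l)
  ff0 <- forearm_frame(p_lm2, straight$p_r, straight$p_u)
  expect_equal(ff0$uy, hf$uy, tolerance = 1e-12)   # straight arm: fy = uy
  expect_equal(flexion_angle(hf, ff0), 0, tolerance = 1e-9)

  for (phi in c(45, 90, 135, 170)) {
    lm <- landmarks_at_flexion(phi)
    ff <- forearm_frame(midpoint(lm$p_m, lm$p_l), lm$p_r, lm$p_u)
    expect_equal(flexion_angle(hf, ff), phi, tolerance = 1e-9)
  }
})

test_that("flexion angle is invariant under a common rigid motion", {
  set.seed(31)
  for (i in 1:20) {
    phi <- runif(1, 5, 175)
    lm <- landmarks_at_flexion(phi)
    R <- rodrigues_matrix(rand_unit_vec(), runif(1, -180, 180))
    tr <- rnorm(3, 0, 200)
    lm_m <- lapply(lm, function(p) drop(R %*% p) + tr)
    hf <- humerus_frame(lm_m$p_g, lm_m$p_m, lm_m$p_l)
    ff <- forearm_frame(midpoint(lm_m$p_m, lm_m$p_l), lm_m$p_r, lm_m$p_u)
    expect_equal(flexion_angle(hf, ff), phi, tolerance = 1e-9)
  }
})

test_that("angle_timeseries handles constant poses and empty streams", {
  entry <- function(host, local) list(host = host, local = local,
                                      n_samples = 1L)
  lm <- landmarks_at_flexion(60)
  reg <- landmark_registry(list(
    p_g = entry("humerus", lm$p_g),
    p_m = entry("humerus", lm$p_m),
    p_l = entry("humerus", lm$p_l),
    p_r = entry("forearm", lm$p_r),
    p_u = entry("forearm", lm$p_u)))
  hum <- const_stream(30, c(0, 0, 0), IDENTITY_QUAT, sensor_id = "humerus")
  fore <- const_stream(30, c(0, 0, 0), IDENTITY_QUAT, sensor_id = "forearm")
  s <- angle_timeseries(hum, fore, reg)
  expect_equal(nrow(s), 30)
  expect_equal(s$phi, rep(60, 30), tolerance = 1e-9)

  empty <- pose_stream(numeric(0), matrix(0, 0, 3), matrix(0, 0, 4))
  s0 <- angle_timeseries(empty, fore, reg)
  expect_s3_class(s0, "angle_series")
  expect_equal(nrow(s0), 0)
})

test_that("angle series CSV round-trips", {
  s <- angle_series(seq(0, 1, by = 0.25), c(0, 45.5, 90.123456789, 135, 180))
  path <- withr::local_tempfile(fileext = ".csv")
  write_angle_series(s, path)
  back <- read_angle_series(path)
  expect_equal(back$t, s$t)
  expect_equal(back$phi, s$phi)
})

test_that("angle_series validates its range invariant", {
  expect_error(angle_series(0:1, c(10, 190)), "180")
  expect_error(angle_series(0:1, c(10, NA)), "finite")
  expect_error(angle_series(0:2, c(1, 2)), "length")
})
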
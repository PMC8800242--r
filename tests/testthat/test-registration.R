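# Landmark digitization and reconstruction.

test_that("digitize_landmark recovers the landmark in the host frame", {
  # identity host, stylus sitting at (30,0,0): local is the world position
  host <- const_stream(1, c(0, 0, 0), IDENTITY_QUAT, sensor_id = "humerus")
  stylus <- const_stream(1, c(30, 0, 0), IDENTITY_QUAT, sensor_id = "stylus")
  e <- digitize_landmark(stylus, host, "p_g")
  expect_equal(e$local, c(30, 0, 0))
  expect_identical(e$host, "humerus")
  expect_identical(e$n_samples, 1L)

  # translated host: world (130,0,0) with host at (100,0,0) -> local (30,0,0)
  host2 <- const_stream(1, c(100, 0, 0), IDENTITY_QUAT)
  stylus2 <- const_stream(1, c(130, 0, 0), IDENTITY_QUAT)
  expect_equal(digitize_landmark(stylus2, host2, "p_m")$local, c(30, 0, 0))

  # rotated host, checked against the transform oracle
  set.seed(5)
  ax <- rand_unit_vec(); ang <- 73
  q <- quat_from_axis_angle(ax, ang)
  hostp <- c(12, -40, 7)
  local_true <- c(3, 8, -5)
  world <- drop(rodrigues_matrix(ax, ang) %*% local_true) + hostp
  host3 <- const_stream(4, hostp, q)
  stylus3 <- const_stream(4, world, IDENTITY_QUAT)
  expect_equal(digitize_landmark(stylus3, host3, "p_l")$local, local_true,
               tolerance = 1e-10)
})

test_that("digitize_landmark validates windows and alignment", {
  host <- const_stream(5, c(0, 0, 0), IDENTITY_QUAT)
  empty <- pose_stream(numeric(0), matrix(0, 0, 3), matrix(0, 0, 4))
  expect_error(digitize_landmark(empty, host, "p_g"), "empty")
  expect_error(digitize_landmark(host, empty, "p_g"), "empty")
  # stylus window shifted by more than half a sample period
  late <- const_stream(5, c(0, 0, 0), IDENTITY_QUAT, t0 = 1)
  expect_error(digitize_landmark(late, host, "p_g"), "misaligned")
})

test_that("averaging 60 noisy samples localizes the tip within 0.5 mm", {
  truth <- c(25, -10, 40)
  host <- const_stream(60, c(0, 0, 0), IDENTITY_QUAT, sensor_id = "humerus")
  errs <- vapply(1:50, function(s) {
    set.seed(s)
    tip <- matrix(truth, 60, 3, byrow = TRUE) + matrix(rnorm(180, 0, 0.76), 60, 3)
    stylus <- pose_stream(seq_len(60) / 60, tip,
                          matrix(IDENTITY_QUAT, 60, 4, byrow = TRUE),
                          sensor_id = "stylus")
    sqrt(sum((digitize_landmark(stylus, host, "p_g")$local - truth)^2))
  }, numeric(1))
  # P(||mean - truth|| > 0.5) ~ 1e-5 per seed; all 50 must clear it
  expect_true(all(errs < 0.5))
})

test_that("registry enforces completeness and the landmark-host mapping", {
  entry <- function(host, local) list(host = host, local = local,
                                      n_samples = 1L)
  good <- list(p_g = entry("humerus", c(0, 0, 300)),
               p_m = entry("humerus", c(-30, 0, 0)),
               p_l = entry("humerus", c(30, 0, 0)),
               p_r = entry("forearm", c(25, 0, 0)),
               p_u = entry("forearm", c(-25, 0, 0)))
  reg <- landmark_registry(good)
  expect_s3_class(reg, "landmark_registry")

  expect_error(landmark_registry(good[-2]), "p_m")
  bad <- good
  bad$p_r$host <- "humerus"
  expect_error(landmark_registry(bad), "forearm")
})

test_that("reconstruction round-trips digitization and follows the host pose", {
  entry <- function(host, local) list(host = host, local = local,
                                      n_samples = 1L)
  reg <- landmark_registry(list(
    p_g = entry("humerus", c(0, 0, 300)),
    p_m = entry("humerus", c(-30, 0, 0)),
    p_l = entry("humerus", c(30, 0, 0)),
    p_r = entry("forearm", c(25, 0, -250)),
    p_u = entry("forearm", c(-25, 0, -250))))
  id <- rigid_pose(0, c(0, 0, 0), IDENTITY_QUAT)

  # both poses identity: reconstruction returns the stored locals
  lm <- reconstruct_landmarks(reg, id, id)
  expect_equal(lm$p_g, c(0, 0, 300))
  expect_equal(lm$p_u, c(-25, 0, -250))

  # rotating only the forearm sensor moves only the wrist landmarks
  q90 <- quat_from_axis_angle(c(1, 0, 0), 90)
  lm2 <- reconstruct_landmarks(reg, id, rigid_pose(0, c(0, 0, 0), q90))
  expect_equal(lm2$p_g, lm$p_g)
  expect_equal(lm2$p_m, lm$p_m)
  expect_equal(lm2$p_l, lm$p_l)
  expect_equal(lm2$p_r, drop(rodrigues_matrix(c(1, 0, 0), 90) %*% lm$p_r),
               tolerance = 1e-10)

  # noiseless digitize -> reconstruct at the digitization pose is identity
  set.seed(9)
  for (i in 1:10) {
    hum_pose <- rand_pose()
    fore_pose <- rand_pose()
    world <- list(p_g = rnorm(3, 0, 100), p_m = rnorm(3, 0, 100),
                  p_l = rnorm(3, 0, 100), p_r = rnorm(3, 0, 100),
                  p_u = rnorm(3, 0, 100))
    entries <- lapply(setNames(LANDMARK_IDS, LANDMARK_IDS), function(id2) {
      host_pose <- if (id2 %in% c("p_g", "p_m", "p_l")) hum_pose else fore_pose
      host <- const_stream(1, host_pose$position, host_pose$orientation)
      stylus <- const_stream(1, world[[id2]], IDENTITY_QUAT)
      digitize_landmark(stylus, host, id2)
    })
    reg_i <- landmark_registry(entries)
    back <- reconstruct_landmarks(reg_i, hum_pose, fore_pose)
    err <- max(vapply(LANDMARK_IDS, function(id2) {
      sqrt(sum((back[[id2]] - world[[id2]])^2))
    }, numeric(1)))
    expect_lt(err, 1e-9)
  }
})

test_that("within-bone landmark distances are invariant under motion", {
  entry <- function(host, local) list(host = host, local = local,
                                      n_samples = 1L)
  reg <- landmark_registry(list(
    p_g = entry("humerus", c(0, 0, 300)),
    p_m = entry("humerus", c(-30, 0, 0)),
    p_l = entry("humerus", c(30, 0, 0)),
    p_r = entry("forearm", c(25, 0, -250)),
    p_u = entry("forearm", c(-25, 0, -250))))
  set.seed(21)
  d0 <- NULL
  for (i in 1:20) {
    lm <- reconstruct_landmarks(reg, rand_pose(), rand_pose())
    d <- c(sqrt(sum((lm$p_g - lm$p_m)^2)), sqrt(sum((lm$p_g - lm$p_l)^2)),
           sqrt(sum((lm$p_m - lm$p_l)^2)), sqrt(sum((lm$p_r - lm$p_u)^2)))
    if (is.null(d0)) d0 <- d else expect_equal(d, d0, tolerance = 1e-9)
  }
})

test_that("registry JSON serialization round-trips", {
  entry <- function(host, local) list(host = host, local = local,
                                      n_samples = 17L)
  reg <- landmark_registry(list(
    p_g = entry("humerus", c(0.123456789, 0, 300)),
    p_m = entry("humerus", c(-30, 1e-7, 0)),
    p_l = entry("humerus", c(30, 0, 0)),
    p_r = entry("forearm", c(25, 0, -250)),
    p_u = entry("forearm", c(-25, 0, -250))))
  path <- withr::local_tempfile(fileext = ".json")
  write_landmark_registry(reg, path)
  back <- read_landmark_registry(path)
  for (id in LANDMARK_IDS) {
    expect_equal(back[[id]]$local, reg[[id]]$local)
    expect_identical(back[[id]]$host, reg[[id]]$host)
  }
})
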
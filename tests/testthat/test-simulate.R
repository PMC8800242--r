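# Trial simulator: determinism, noiseless limit, noise calibration,
# parameter recovery, soft-tissue artifact structure.

noiseless_cfg <- function(seed = 1L) {
  sim_config(pos_noise_rms = 0, ori_noise_rms = 0, hold_sd_deg = 0,
             digitization_noise_mm = 0, xray_noise_sd_deg = 0,
             artifact_gain = 0, seed = seed)
}

test_that("identical config and seed reproduce a trial exactly", {
  cfg <- sim_config(seed = 123L)
  t1 <- simulate_model_bone_trial(cfg)
  t2 <- simulate_model_bone_trial(cfg)
  expect_identical(t1$humerus_stream$position, t2$humerus_stream$position)
  expect_identical(t1$forearm_stream$orientation,
                   t2$forearm_stream$orientation)
  expect_identical(t1$truth$phi, t2$truth$phi)
  expect_identical(lapply(unclass(t1$registry), `[[`, "local"),
                   lapply(unclass(t2$registry), `[[`, "local"))

  t3 <- simulate_model_bone_trial(sim_config(seed = 124L))
  expect_false(identical(t1$forearm_stream$position,
                         t3$forearm_stream$position))
})

test_that("noiseless simulation recovers the commanded trajectory", {
  trial <- simulate_model_bone_trial(noiseless_cfg())
  s <- angle_timeseries(trial$humerus_stream, trial$forearm_stream,
                        trial$registry)
  expect_equal(nrow(s), nrow(trial$truth))
  expect_lt(max(abs(s$phi - trial$truth$phi)), 1e-6)
  expect_equal(trial$hold_targets, c(0, 45, 90, 135))
})

test_that("injected position noise has the configured RMS", {
  set.seed(55)
  e <- elbowrom:::.position_noise(20000, 0.76)
  rms <- sqrt(mean(rowSums(e^2)))
  expect_lt(abs(rms - 0.76) / 0.76, 0.05)
})

test_that("injected orientation noise has the configured RMS angle", {
  set.seed(56)
  q <- elbowrom:::.orientation_noise(20000, 0.15)
  ang <- 2 * acos(pmin(1, q[, 1])) * 180 / pi
  expect_lt(abs(sqrt(mean(ang^2)) - 0.15) / 0.15, 0.05)
})

test_that("hold variability is recoverable from plateau spread", {
  cfg <- sim_config(seed = 61L)
  nominal <- c(0, 45, 90, 135)
  measured <- matrix(NA_real_, 4, 100)
  for (i in 1:100) {
    cfg_i <- cfg
    cfg_i$seed <- elbowrom:::.sub_seed(cfg$seed, i)
    trial <- simulate_model_bone_trial(cfg_i, nominal)
    s <- angle_timeseries(trial$humerus_stream, trial$forearm_stream,
                          trial$registry)
    pl <- match_to_nominal(detect_plateaus(s), nominal)
    for (j in seq_along(nominal)) {
      hit <- which(!is.na(pl$nominal_deg) & pl$nominal_deg == nominal[j])
      if (length(hit) == 1L) measured[j, i] <- pl$mean_deg[hit]
    }
  }
  expect_false(anyNA(measured))
  # pooled across the three unclamped targets (the 0 deg hold is truncated
  # at the extension stop, which shrinks its spread)
  est <- sqrt(mean(apply(measured[2:4, ], 1, var)))
  expect_lt(abs(est - cfg$hold_sd_deg) / cfg$hold_sd_deg, 0.2)
})

test_that("in-vivo trial without artifact agrees with truth at the holds", {
  cfg <- noiseless_cfg(seed = 71L)
  cfg$pos_noise_rms <- 0.76
  cfg$ori_noise_rms <- 0.15
  cfg$digitization_noise_mm <- 0.76
  trial <- simulate_in_vivo_trial(cfg, c(5, 130))
  s <- angle_timeseries(trial$humerus_stream, trial$forearm_stream,
                        trial$registry)
  pl <- detect_plateaus(s)
  expect_equal(nrow(pl), 2)
  meas <- sort(pl$mean_deg)
  expect_lt(max(abs(meas - trial$hold_targets)), 0.5)
})

test_that("soft-tissue artifact produces flexion-dominant, proportional error", {
  rep <- run_validation_experiment(sim_config(seed = 7L), "in_vivo",
                                   n_reps = 3, n_raters = 2)
  d <- rep$pairs
  expect_equal(nrow(d[d$position == "flexion", ]), 36)
  sd_flex <- rep$per_position$flexion$bland_altman$sd_diff_deg
  sd_ext <- rep$per_position$extension$bland_altman$sd_diff_deg
  expect_gt(sd_flex, sd_ext)
  # |difference| grows with the measured magnitude (proportional error)
  ad <- abs(d$ems_deg - d$xray_deg)
  m <- (d$ems_deg + d$xray_deg) / 2
  expect_gt(unname(coef(lm(ad ~ m))[2]), 0)
})

test_that("simulator validates configuration and arguments", {
  expect_error(sim_config(rate_hz = -1), "positive")
  expect_error(sim_config(pos_noise_rms = -0.1), "non-negative")
  expect_error(simulate_in_vivo_trial(sim_config(), c(130, 5)),
               "extension < flexion")
  expect_error(simulate_model_bone_trial(sim_config(), nominal = c(-5, 45)),
               "0, 180")
  expect_error(run_validation_experiment(sim_config(), "model_bone",
                                         n_reps = 0), "at least 2")
})

test_that("sim_config YAML round-trips", {
  cfg <- sim_config(seed = 99L, artifact_gain = 0.05)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(unclass(back), unclass(cfg))
})
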
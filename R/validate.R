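# End-to-end validation harness: run simulated trials through the full
# measurement pipeline (registry -> angle series -> plateaus) and assemble
# the accuracy/reliability statistics a validation study reports: per-angle
# means and SDs, Pearson correlation, Bland-Altman limits, and intra-/
# inter-rater ICCs.

# Measured plateau angle per nominal for one model-bone trial.
.measure_model_bone_trial <- function(trial, nominal) {
  series <- angle_timeseries(trial$humerus_stream, trial$forearm_stream,
                             trial$registry)
  pl <- match_to_nominal(detect_plateaus(series), nominal = nominal)
  out <- rep(NA_real_, length(nominal))
  for (j in seq_along(nominal)) {
    hit <- which(!is.na(pl$nominal_deg) & pl$nominal_deg == nominal[j])
    if (length(hit) == 1L) out[j] <- pl$mean_deg[hit]
  }
  out
}

# Extension/flexion plateau means for one in-vivo trial (the analysis does
# not see the truth: extremes are the min and max plateau).
.measure_in_vivo_trial <- function(trial) {
  series <- angle_timeseries(trial$humerus_stream, trial$forearm_stream,
                             trial$registry)
  pl <- detect_plateaus(series)
  if (nrow(pl) < 1L) {
    stop("no plateau detected in simulated in-vivo trial", call. = FALSE)
  }
  c(extension = min(pl$mean_deg), flexion = max(pl$mean_deg))
}

.mean_icc <- function(mats, model, unit) {
  res <- lapply(mats, icc, model = model, unit = unit)
  est <- mean(vapply(res, `[[`, numeric(1), "estimate"))
  ci <- rowMeans(vapply(res, `[[`, numeric(2), "ci95"))
  list(estimate = est, ci95 = ci, k = res[[1L]]$k, model = model,
       unit = unit, per_rater = res)
}

#' Run a full simulated validation experiment
#'
#' `model_bone` mode reproduces the bench protocol: `n_raters` simulated
#' examiners each flex the model arm `n_reps` times through the four
#' nominal angles; plateau means are compared with the nominals (per-angle
#' mean and SD, pooled Pearson r) and reliability is summarized with
#' one-way (intra-rater) and two-way random (inter-rater) ICCs.
#'
#' `in_vivo` mode simulates `n_subjects` participants whose true extremes
#' are drawn around typical extension/flexion values; each is measured
#' `n_reps` times by `n_raters` raters with soft-tissue artifact, paired
#' with noisy radiographic readings, and summarized per position with
#' Pearson r and Bland-Altman limits plus ICCs.
#'
#' All randomness derives from `cfg$seed`; results are reproducible
#' byte-for-byte.
#'
#' @param cfg A `sim_config`.
#' @param mode `"model_bone"` or `"in_vivo"`.
#' @param n_reps Repetitions per rater (>= 2).
#' @param n_raters Number of raters (>= 1; inter-rater ICC needs >= 2).
#' @param nominal Nominal angles for model-bone mode.
#' @param n_subjects Number of simulated participants (in-vivo mode).
#' @return An object of class `validation_report`.
#' @export
run_validation_experiment <- function(cfg, mode = c("model_bone", "in_vivo"),
                                      n_reps = 10, n_raters = 2,
                                      nominal = c(0, 45, 90, 135),
                                      n_subjects = 6) {
  stopifnot(inherits(cfg, "sim_config"))
  mode <- match.arg(mode)
  if (!is.numeric(n_reps) || n_reps < 2L) {
    stop("n_reps must be at least 2", call. = FALSE)
  }
  if (!is.numeric(n_raters) || n_raters < 1L) {
    stop("n_raters must be at least 1", call. = FALSE)
  }
  n_reps <- as.integer(n_reps); n_raters <- as.integer(n_raters)

  if (mode == "model_bone") {
    .validate_model_bone(cfg, n_reps, n_raters, nominal)
  } else {
    .validate_in_vivo(cfg, n_reps, n_raters, as.integer(n_subjects))
  }
}

.validate_model_bone <- function(cfg, n_reps, n_raters, nominal) {
  m <- length(nominal)
  # measured[j, rep, rater]
  measured <- array(NA_real_, dim = c(m, n_reps, n_raters))
  idx <- 0L
  trials <- list()
  for (rater in seq_len(n_raters)) {
    for (rep_i in seq_len(n_reps)) {
      idx <- idx + 1L
      cfg_i <- cfg
      cfg_i$seed <- .sub_seed(cfg$seed, idx)
      trial <- simulate_model_bone_trial(cfg_i, nominal)
      measured[, rep_i, rater] <- .measure_model_bone_trial(trial, nominal)
      trials[[idx]] <- list(rater = rater, rep = rep_i,
                            measured = measured[, rep_i, rater])
    }
  }
  if (anyNA(measured)) {
    stop("some trials produced no matched plateau for a nominal angle",
         call. = FALSE)
  }

  flat <- matrix(measured, nrow = m)   # m x (n_reps * n_raters)
  per_nominal <- data.frame(
    nominal_deg = nominal,
    mean_deg = rowMeans(flat),
    sd_deg = apply(flat, 1L, stats::sd),
    n = ncol(flat)
  )
  errors <- per_nominal$mean_deg - nominal

  pooled_nominal <- rep(nominal, times = ncol(flat))
  pooled_measured <- as.vector(flat)
  pearson_res <- pearson(pooled_nominal, pooled_measured)

  intra_mats <- lapply(seq_len(n_raters), function(r) {
    measured[, , r, drop = TRUE]
  })
  icc_intra_avg <- .mean_icc(intra_mats, "oneway", "average_k")
  icc_intra_single <- .mean_icc(intra_mats, "oneway", "single")

  icc_inter_avg <- NULL
  icc_inter_single <- NULL
  if (n_raters >= 2L) {
    rater_means <- apply(measured, c(1L, 3L), mean)  # m x n_raters
    icc_inter_avg <- icc(rater_means, "twoway_random", "average_k")
    icc_inter_single <- icc(rater_means, "twoway_random", "single")
  }

  structure(list(
    mode = "model_bone",
    nominal = nominal,
    per_nominal = per_nominal,
    max_abs_error_deg = max(abs(errors)),
    max_sd_deg = max(per_nominal$sd_deg),
    pearson = pearson_res,
    icc = list(intra_avg = icc_intra_avg, intra_single = icc_intra_single,
               inter_avg = icc_inter_avg, inter_single = icc_inter_single),
    pairs = data.frame(nominal_deg = pooled_nominal,
                       measured_deg = pooled_measured),
    n_reps = n_reps, n_raters = n_raters,
    config = cfg
  ), class = "validation_report")
}

.validate_in_vivo <- function(cfg, n_reps, n_raters, n_subjects) {
  if (n_subjects < 2L) stop("n_subjects must be at least 2", call. = FALSE)
  # subject true extremes around typical adult values
  set.seed(.sub_seed(cfg$seed, 0L))
  ext_true <- pmax(0, stats::rnorm(n_subjects, 2.7, 2.0))
  flex_true <- pmin(180, stats::rnorm(n_subjects, 130.8, 4.5))

  rows <- list()
  idx <- 0L
  for (s in seq_len(n_subjects)) {
    for (rater in seq_len(n_raters)) {
      for (rep_i in seq_len(n_reps)) {
        idx <- idx + 1L
        cfg_i <- cfg
        cfg_i$seed <- .sub_seed(cfg$seed, idx)
        trial <- simulate_in_vivo_trial(cfg_i, c(ext_true[s], flex_true[s]))
        meas <- .measure_in_vivo_trial(trial)
        rows[[idx]] <- data.frame(
          subject = s, rater = rater, rep = rep_i,
          position = c("extension", "flexion"),
          ems_deg = unname(meas),
          xray_deg = trial$xray_readings,
          truth_deg = trial$hold_targets
        )
      }
    }
  }
  pairs <- do.call(rbind, rows)

  per_position <- lapply(c("extension", "flexion"), function(pos) {
    sub <- pairs[pairs$position == pos, ]
    list(position = pos,
         n = nrow(sub),
         ems_mean = mean(sub$ems_deg), ems_sd = stats::sd(sub$ems_deg),
         xray_mean = mean(sub$xray_deg), xray_sd = stats::sd(sub$xray_deg),
         pearson = pearson(sub$ems_deg, sub$xray_deg),
         bland_altman = bland_altman(sub$ems_deg, sub$xray_deg))
  })
  names(per_position) <- c("extension", "flexion")

  # reliability of the EMS flexion measurement: intra-rater as one-way ICC
  # on subject x rep matrices per rater, inter-rater as two-way random ICC
  # on subject x rater means
  flex <- pairs[pairs$position == "flexion", ]
  intra_mats <- lapply(seq_len(n_raters), function(r) {
    sub <- flex[flex$rater == r, ]
    matrix(sub$ems_deg[order(sub$subject, sub$rep)], nrow = n_subjects,
           byrow = TRUE)
  })
  icc_intra <- .mean_icc(intra_mats, "oneway", "average_k")
  icc_inter <- NULL
  if (n_raters >= 2L) {
    rater_means <- vapply(seq_len(n_raters), function(r) {
      sub <- flex[flex$rater == r, ]
      tapply(sub$ems_deg, sub$subject, mean)
    }, numeric(n_subjects))
    icc_inter <- icc(rater_means, "twoway_random", "average_k")
  }

  structure(list(
    mode = "in_vivo",
    pairs = pairs,
    per_position = per_position,
    icc = list(intra_avg = icc_intra, inter_avg = icc_inter),
    n_reps = n_reps, n_raters = n_raters, n_subjects = n_subjects,
    config = cfg
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("== Validation report (%s mode) ==\n", x$mode))
  if (x$mode == "model_bone") {
    cat(sprintf("%d raters x %d reps at nominal angles %s deg\n",
                x$n_raters, x$n_reps, paste(x$nominal, collapse = ", ")))
    df <- x$per_nominal
    for (i in seq_len(nrow(df))) {
      cat(sprintf("  %5.1f deg: mean %7.2f, SD %5.2f (n = %d)\n",
                  df$nominal_deg[i], df$mean_deg[i], df$sd_deg[i], df$n[i]))
    }
    cat(sprintf("max |mean error| = %.3f deg, max SD = %.3f deg\n",
                x$max_abs_error_deg, x$max_sd_deg))
    print(x$pearson)
    cat(sprintf("intra-rater ICC(1,%d) = %.4f, inter-rater ICC(2,%d) = %.4f\n",
                x$icc$intra_avg$k, x$icc$intra_avg$estimate,
                if (is.null(x$icc$inter_avg)) NA else x$icc$inter_avg$k,
                if (is.null(x$icc$inter_avg)) NA
                else x$icc$inter_avg$estimate))
  } else {
    cat(sprintf("%d subjects, %d raters x %d reps, %d paired measurements/position\n",
                x$n_subjects, x$n_raters, x$n_reps,
                x$per_position$extension$n))
    for (pos in c("extension", "flexion")) {
      p <- x$per_position[[pos]]
      cat(sprintf("  %s: EMS %.1f +/- %.1f deg, radiographic %.1f +/- %.1f deg\n",
                  pos, p$ems_mean, p$ems_sd, p$xray_mean, p$xray_sd))
      cat("    "); print(p$bland_altman)
    }
  }
  invisible(x)
}

# Flatten a validation report for JSON serialization.
.validation_report_to_list <- function(x) {
  icc_item <- function(ic) {
    if (is.null(ic)) return(NULL)
    list(model = ic$model, unit = ic$unit, k = ic$k,
         estimate = ic$estimate, ci95 = ic$ci95)
  }
  if (x$mode == "model_bone") {
    list(mode = x$mode,
         per_nominal = x$per_nominal,
         max_abs_error_deg = x$max_abs_error_deg,
         max_sd_deg = x$max_sd_deg,
         pearson = list(r = x$pearson$r, p = x$pearson$p_two_sided,
                        n = x$pearson$n, category = x$pearson$category),
         icc = Filter(Negate(is.null), lapply(x$icc, icc_item)),
         n_reps = x$n_reps, n_raters = x$n_raters)
  } else {
    pos_item <- function(p) {
      list(n = p$n, ems_mean = p$ems_mean, ems_sd = p$ems_sd,
           xray_mean = p$xray_mean, xray_sd = p$xray_sd,
           pearson_r = p$pearson$r, pearson_p = p$pearson$p_two_sided,
           bland_altman = p$bland_altman[c("mean_diff_deg", "sd_diff_deg",
                                           "upper_loa_deg", "lower_loa_deg",
                                           "half_width_deg")])
    }
    list(mode = x$mode,
         extension = pos_item(x$per_position$extension),
         flexion = pos_item(x$per_position$flexion),
         icc = Filter(Negate(is.null), lapply(x$icc, icc_item)),
         n_reps = x$n_reps, n_raters = x$n_raters,
         n_subjects = x$n_subjects)
  }
}

#' Write a validation report to a directory (JSON + CSV tables)
#'
#' Writes `report.json` plus, for model-bone reports, `per_nominal.csv` and
#' `pairs.csv`; for in-vivo reports, `pairs.csv`.
#'
#' @param report A `validation_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_validation_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(.validation_report_to_list(report),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  if (report$mode == "model_bone") {
    utils::write.csv(report$per_nominal, file.path(dir, "per_nominal.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  utils::write.csv(report$pairs, file.path(dir, "pairs.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
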
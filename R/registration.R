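# Landmark digitization and registration.
#
# Five bony landmarks are digitized with a hand-held stylus sensor while two
# further sensors stay fixed to the humerus and the forearm. Each landmark is
# stored in the local frame of its host bone sensor, so it can be
# reconstructed in world coordinates at any later time step from that
# sensor's pose alone.

#' The five bony landmark identifiers
#'
#' `p_g` greater tubercle of the humerus, `p_m`/`p_l` medial/lateral
#' epicondyle, `p_r`/`p_u` radial/ulnar styloid process.
#' @export
LANDMARK_IDS <- c("p_g", "p_m", "p_l", "p_r", "p_u")

# Fixed landmark -> bone-sensor assignment. The humeral landmarks must ride
# on the humerus sensor, the wrist landmarks on the forearm sensor; with the
# forearm locked in supination during trials, the radial styloid is rigid
# with the forearm sensor too.
LANDMARK_HOSTS <- c(p_g = "humerus", p_m = "humerus", p_l = "humerus",
                    p_r = "forearm", p_u = "forearm")

#' Assemble a landmark registry
#'
#' @param entries Named list keyed by landmark id; each element a list with
#'   `host` (`"humerus"` or `"forearm"`), `local` (length-3, mm in the host
#'   sensor frame) and `n_samples` (count of digitization samples averaged).
#' @return An object of class `landmark_registry`.
#' @export
landmark_registry <- function(entries) {
  missing <- setdiff(LANDMARK_IDS, names(entries))
  if (length(missing) > 0L) {
    stop("landmark registry is missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  entries <- entries[LANDMARK_IDS]
  for (id in LANDMARK_IDS) {
    e <- entries[[id]]
    if (!identical(e$host, unname(LANDMARK_HOSTS[[id]]))) {
      stop(sprintf("landmark %s must be hosted by the %s sensor, got '%s'",
                   id, LANDMARK_HOSTS[[id]], e$host), call. = FALSE)
    }
    entries[[id]]$local <- .check_vec3(e$local, paste0("local of ", id))
    entries[[id]]$n_samples <- as.integer(e$n_samples %||% 1L)
  }
  structure(entries, class = "landmark_registry")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.landmark_registry <- function(x, ...) {
  cat("<landmark_registry>\n")
  for (id in LANDMARK_IDS) {
    e <- x[[id]]
    cat(sprintf("  %-4s on %-7s local = (%8.3f, %8.3f, %8.3f) mm  [n=%d]\n",
                id, e$host, e$local[1L], e$local[2L], e$local[3L],
                e$n_samples))
  }
  invisible(x)
}

# Nearest-timestamp pairing of two streams: for each time in `ts`, index of
# the nearest sample of `stream`; errors when the gap exceeds half a period.
.align_to <- function(ts, stream, what = "stream") {
  if (length(stream) == 0L) stop("empty ", what, call. = FALSE)
  idx <- findInterval(ts, stream$t, all.inside = FALSE)
  idx <- pmax(idx, 1L)
  idx_hi <- pmin(idx + 1L, length(stream$t))
  use_hi <- abs(stream$t[idx_hi] - ts) < abs(stream$t[idx] - ts)
  idx[use_hi] <- idx_hi[use_hi]
  gap <- abs(stream$t[idx] - ts)
  max_gap <- 0.5 / stream$rate_hz
  if (any(gap > max_gap + 1e-12)) {
    stop(sprintf("streams misaligned: gap %.4f s exceeds half a sample period (%.4f s)",
                 max(gap), max_gap), call. = FALSE)
  }
  idx
}

#' Digitize one landmark from a stylus window
#'
#' Pairs each stylus sample with the nearest host-sensor sample, maps the
#' stylus tip into the host sensor frame, and averages. The stylus tip
#' defaults to the stylus sensor origin; a fixed tip offset (stylus-local,
#' mm) may be supplied for a calibrated stylus.
#'
#' @param stylus `pose_stream` window of the digitizing sensor.
#' @param host `pose_stream` window of the bone-fixed host sensor.
#' @param id Landmark identifier (one of [LANDMARK_IDS]).
#' @param tip_offset Stylus-local tip offset (mm), default `c(0, 0, 0)`.
#' @return A registry entry: list with `host`, `local`, `n_samples`.
#' @export
digitize_landmark <- function(stylus, host, id, tip_offset = c(0, 0, 0)) {
  id <- match.arg(id, LANDMARK_IDS)
  if (length(stylus) == 0L) stop("empty stylus window", call. = FALSE)
  if (length(host) == 0L) stop("empty host window", call. = FALSE)
  tip_offset <- .check_vec3(tip_offset, "tip_offset")
  idx <- .align_to(stylus$t, host, "host window")

  # stylus tip in world coordinates, all samples at once
  tips <- quat_rotate_rows(stylus$orientation,
                           matrix(tip_offset, nrow = length(stylus),
                                  ncol = 3L, byrow = TRUE)) + stylus$position
  # into the host sensor frame
  hq <- host$orientation[idx, , drop = FALSE]
  hq_conj <- cbind(hq[, 1L], -hq[, 2:4, drop = FALSE])
  locals <- quat_rotate_rows(hq_conj, tips - host$position[idx, , drop = FALSE])
  list(host = unname(LANDMARK_HOSTS[[id]]),
       local = colMeans(locals),
       n_samples = nrow(locals))
}

#' Reconstruct all landmark world positions at one time step
#'
#' Each landmark is mapped through its host sensor's current pose.
#'
#' @param reg A `landmark_registry`.
#' @param humerus `rigid_pose` of the humerus sensor.
#' @param forearm `rigid_pose` of the forearm sensor.
#' @return Named list of length-3 world positions (mm), one per landmark.
#' @export
reconstruct_landmarks <- function(reg, humerus, forearm) {
  if (!inherits(reg, "landmark_registry")) {
    missing <- setdiff(LANDMARK_IDS, names(reg))
    if (length(missing) > 0L) {
      stop("missing landmark: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }
  out <- vector("list", length(LANDMARK_IDS))
  names(out) <- LANDMARK_IDS
  for (id in LANDMARK_IDS) {
    e <- reg[[id]]
    if (is.null(e)) stop("missing landmark: ", id, call. = FALSE)
    pose <- if (identical(e$host, "humerus")) humerus else forearm
    out[[id]] <- transform_point(pose, e$local)
  }
  out
}

# Vectorized reconstruction over aligned streams: returns a named list of
# n x 3 world-position matrices, one per landmark.
.reconstruct_landmarks_rows <- function(reg, hum_pos, hum_q, fore_pos, fore_q) {
  n <- nrow(hum_pos)
  out <- vector("list", length(LANDMARK_IDS))
  names(out) <- LANDMARK_IDS
  for (id in LANDMARK_IDS) {
    e <- reg[[id]]
    if (identical(e$host, "humerus")) {
      P <- hum_pos; Q <- hum_q
    } else {
      P <- fore_pos; Q <- fore_q
    }
    L <- matrix(e$local, nrow = n, ncol = 3L, byrow = TRUE)
    out[[id]] <- quat_rotate_rows(Q, L) + P
  }
  out
}

#' Write a landmark registry to JSON
#'
#' Format: `{landmark: {host, local_mm: [x, y, z], n_samples}}`.
#'
#' @param reg A `landmark_registry`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_landmark_registry <- function(reg, path) {
  obj <- lapply(unclass(reg), function(e) {
    list(host = e$host, local_mm = e$local, n_samples = e$n_samples)
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a landmark registry from JSON
#' @param path File written by [write_landmark_registry()].
#' @return A `landmark_registry`.
#' @export
read_landmark_registry <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  entries <- lapply(obj, function(e) {
    list(host = e$host, local = as.numeric(e$local_mm),
         n_samples = e$n_samples)
  })
  landmark_registry(entries)
}
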
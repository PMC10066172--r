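#' Trajectory constructor
#'
#' A time-stamped 2-D path in canonical coordinates: time in seconds
#' (strictly increasing, starting at or after 0), positions in cm with the
#' cool spot at the origin, plus the nominal frame rate. Duration-based
#' computations always use the actual median frame interval, never the
#' nominal fps.
#'
#' @param t,x,y equal-length numeric vectors (seconds, cm, cm).
#' @param fps nominal frames per second.
#' @return a data.frame of class `trajectory` with columns `t`, `x`, `y` and
#'   attribute `fps`.
#' @export
trajectory <- function(t, x, y, fps = 30) {
  if (length(t) != length(x) || length(t) != length(y))
    stop("t, x, y must have equal lengths")
  if (any(!is.finite(t)) || any(!is.finite(x)) || any(!is.finite(y)))
    stop("trajectory contains non-finite values")
  if (length(t) > 1 && any(diff(t) <= 0)) stop("t must be strictly increasing")
  if (t[1] < 0) stop("t must start at or after 0")
  out <- data.frame(t = t, x = x, y = y)
  attr(out, "fps") <- fps
  class(out) <- c("trajectory", "data.frame")
  out
}

#' Median frame interval of a trajectory, seconds
#' @param traj a trajectory.
#' @export
frame_interval <- function(traj) {
  if (nrow(traj) < 2) return(1 / attr(traj, "fps"))
  stats::median(diff(traj$t))
}

#' Trial recording constructor
#'
#' Couples a trajectory with its arena and trial identity. Sessions in this
#' paradigm consist of 10 five-minute trials per animal.
#'
#' @param traj a [trajectory()].
#' @param arena the arena the animal navigated.
#' @param animal_id animal identifier string.
#' @param trial_index trial number within the session, 1..10.
#' @param condition `"heated"`, `"unheated"` or `"blinded"`.
#' @param trial_s nominal trial duration, seconds.
#' @return an object of class `trial_recording`.
#' @export
trial_recording <- function(traj, arena, animal_id = "a1", trial_index = 1L,
                            condition = c("heated", "unheated", "blinded"),
                            trial_s = 300) {
  condition <- match.arg(condition)
  stopifnot(inherits(traj, "trajectory"), inherits(arena, "arena"))
  if (trial_index < 1 || trial_index > 10)
    stop("trial_index must lie in 1..10")
  dur <- traj$t[nrow(traj)] - traj$t[1] + frame_interval(traj)
  if (dur > trial_s * 1.05)
    stop(sprintf("trajectory duration %.1f s exceeds trial duration %g s (+5%%)",
                 dur, trial_s))
  structure(list(trajectory = traj, arena = arena, animal_id = animal_id,
                 trial_index = as.integer(trial_index), condition = condition,
                 trial_s = trial_s),
            class = "trial_recording")
}

tracking_header <- c("frame", "time_s", "x_px", "y_px",
                     "lm1_x", "lm1_y", "lm2_x", "lm2_y",
                     "lm3_x", "lm3_y", "lm4_x", "lm4_y")

#' Read a tracking table
#'
#' Reads the canonical tracking-CSV dialect (header
#' `frame,time_s,x_px,y_px,lm1_x,lm1_y,...,lm4_x,lm4_y`; empty field =
#' missing) or the minimal pre-calibrated 3-column form `time_s,x_cm,y_cm`.
#' Pixel positions are mapped to the canonical cm frame (cool spot at the
#' origin) with the supplied calibration, or with one fitted from the median
#' tracked landmark positions when `calibration` is `NULL`. Missing
#' coordinates are linearly interpolated when the gap does not exceed
#' `max_gap_s`; longer gaps split the recording and the longest contiguous
#' segment is kept with a warning.
#'
#' @param path CSV path.
#' @param arena the arena of the recording.
#' @param calibration optional `calibration`; fitted from landmarks if
#'   absent (full dialect only).
#' @param max_gap_s maximum interpolatable gap, seconds.
#' @param max_missing_frac recordings with a larger fraction of missing
#'   frames are rejected.
#' @param fps nominal frame rate.
#' @inheritParams trial_recording
#' @return a [trial_recording()].
#' @export
read_tracking_table <- function(path, arena, calibration = NULL,
                                max_gap_s = 0.5, max_missing_frac = 0.2,
                                fps = 30, animal_id = "a1", trial_index = 1L,
                                condition = "heated", trial_s = 300) {
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  dat <- utils::read.csv(path, colClasses = "numeric", check.names = FALSE)
  if (identical(header, c("time_s", "x_cm", "y_cm"))) {
    t <- dat$time_s; xy <- cbind(dat$x_cm, dat$y_cm)
  } else if (identical(header, tracking_header)) {
    t <- dat$time_s
    if (is.null(calibration)) {
      lm_px <- matrix(NA_real_, 4, 2)
      for (k in 1:4) {
        lm_px[k, ] <- c(stats::median(dat[[sprintf("lm%d_x", k)]], na.rm = TRUE),
                        stats::median(dat[[sprintf("lm%d_y", k)]], na.rm = TRUE))
      }
      calibration <- calibrate_from_landmarks(lm_px, arena)
    }
    xy <- apply_calibration(cbind(dat$x_px, dat$y_px), calibration)
  } else {
    stop("unparseable tracking header: ", paste(header, collapse = ","))
  }
  miss <- !is.finite(xy[, 1]) | !is.finite(xy[, 2])
  if (mean(miss) > max_missing_frac)
    stop(sprintf("%.0f%% of frames missing exceeds %.0f%% quality threshold",
                 100 * mean(miss), 100 * max_missing_frac))
  dt <- stats::median(diff(t))
  keep <- seq_along(t)
  if (any(miss)) {
    r <- rle(miss)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    long <- which(r$values & r$lengths * dt > max_gap_s)
    if (length(long)) {
      bad <- rep(FALSE, length(t))
      for (g in long) bad[starts[g]:ends[g]] <- TRUE
      seg <- rle(!bad)
      seg_ends <- cumsum(seg$lengths); seg_starts <- seg_ends - seg$lengths + 1L
      ok <- which(seg$values)
      pick <- ok[which.max(seg$lengths[ok])]
      keep <- seg_starts[pick]:seg_ends[pick]
      warning(sprintf("gap > %g s: keeping longest contiguous segment (%d of %d frames)",
                      max_gap_s, length(keep), length(t)))
    }
    for (col in 1:2) {
      xy[keep, col] <- stats::approx(t[keep][!miss[keep]],
                                     xy[keep, col][!miss[keep]],
                                     xout = t[keep], rule = 2)$y
    }
  }
  traj <- trajectory(t[keep], xy[keep, 1], xy[keep, 2], fps = fps)
  trial_recording(traj, arena, animal_id = animal_id,
                  trial_index = trial_index, condition = condition,
                  trial_s = trial_s)
}

#' Write a trajectory in the canonical tracking dialect
#'
#' Positions and landmarks are written in pixel coordinates through the
#' inverse of `calibration` (identity mapping when `NULL`, i.e. px == cm).
#'
#' @param rec a `trial_recording` (or bare `trajectory` plus `arena`).
#' @param path output CSV path.
#' @param calibration the px -> cm calibration the file should imply.
#' @param arena needed when `rec` is a bare trajectory.
#' @export
write_tracking_table <- function(rec, path, calibration = NULL, arena = NULL) {
  if (inherits(rec, "trial_recording")) {
    traj <- rec$trajectory; arena <- rec$arena
  } else traj <- rec
  lm_cm <- arena_landmarks(arena)
  if (is.null(calibration)) {
    xy_px <- cbind(traj$x, traj$y); lm_px <- lm_cm
  } else {
    inv <- invert_calibration(calibration)
    xy_px <- apply_calibration(cbind(traj$x, traj$y), inv)
    lm_px <- apply_calibration(lm_cm, inv)
  }
  n <- nrow(traj)
  out <- data.frame(frame = seq_len(n) - 1L, time_s = traj$t,
                    x_px = xy_px[, 1], y_px = xy_px[, 2])
  for (k in 1:4) {
    out[[sprintf("lm%d_x", k)]] <- rep(lm_px[k, 1], n)
    out[[sprintf("lm%d_y", k)]] <- rep(lm_px[k, 2], n)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Align a trajectory to the cool spot
#'
#' Pure translation putting `spot_center` at the origin; an isometry, so all
#' inter-point distances are preserved.
#'
#' @param traj a trajectory.
#' @param spot_center length-2 point to move to (0, 0).
#' @return the translated trajectory.
#' @export
align_to_spot <- function(traj, spot_center) {
  trajectory(traj$t, traj$x - spot_center[1], traj$y - spot_center[2],
             fps = attr(traj, "fps"))
}

#' Per-frame speed
#'
#' Central-difference speed in cm/s, with one-sided differences at the ends;
#' same length as the trajectory.
#'
#' @param traj a trajectory with at least 2 frames.
#' @return numeric vector, cm/s.
#' @export
speed_series <- function(traj) {
  n <- nrow(traj)
  if (n < 2) stop("speed requires at least 2 frames")
  x <- traj$x; y <- traj$y; t <- traj$t
  v <- numeric(n)
  if (n > 2) {
    i <- 2:(n - 1)
    v[i] <- sqrt((x[i + 1] - x[i - 1])^2 + (y[i + 1] - y[i - 1])^2) /
      (t[i + 1] - t[i - 1])
  }
  v[1] <- sqrt((x[2] - x[1])^2 + (y[2] - y[1])^2) / (t[2] - t[1])
  v[n] <- sqrt((x[n] - x[n - 1])^2 + (y[n] - y[n - 1])^2) / (t[n] - t[n - 1])
  v
}
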
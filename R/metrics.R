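#' On-spot mask
#'
#' A frame counts as on the cool spot when the animal's tracked position
#' (its centroid) lies within the cool-spot disc; the disc is closed, so a
#' point exactly on the spot edge is on-spot.
#'
#' @param rec a `trial_recording`.
#' @return logical vector, one element per frame.
#' @export
on_spot_mask <- function(rec) {
  traj <- rec$trajectory
  ctr <- rec$arena$spot_center
  sqrt((traj$x - ctr[1])^2 + (traj$y - ctr[2])^2) <= rec$arena$spot_radius
}

#' Detect on-spot stays
#'
#' Maximal on-spot runs after bridging brief off-spot interruptions (tracker
#' jitter at the spot edge should not split a bout). Runs lasting at least
#' `min_duration_s` are successful stays; shorter visits are discarded but
#' counted. Durations are frame counts times the median frame interval, so a
#' run of exactly `min_duration_s * fps` frames meets the threshold.
#'
#' @param mask logical on-spot series (from [on_spot_mask()]).
#' @param frame_times time stamps, same length as `mask`.
#' @param min_duration_s minimum stay duration (default 5 s).
#' @param max_gap_s longest off-spot interruption that is bridged.
#' @return data.frame with columns `start_s`, `end_s`, `duration_s`, one row
#'   per successful stay, with attribute `n_short_visits`.
#' @export
detect_stays <- function(mask, frame_times, min_duration_s = 5.0,
                         max_gap_s = 0.2) {
  if (length(mask) != length(frame_times))
    stop("mask and frame_times must have equal length")
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      duration_s = numeric(0))
  attr(empty, "n_short_visits") <- 0L
  if (!any(mask)) return(empty)
  dt <- if (length(frame_times) > 1) stats::median(diff(frame_times)) else
    min_duration_s
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  # bridge interior off-runs no longer than max_gap_s
  bridged <- mask
  for (g in which(!r$values & r$lengths * dt <= max_gap_s)) {
    if (g > 1 && g < length(r$values)) bridged[starts[g]:ends[g]] <- TRUE
  }
  r <- rle(as.logical(bridged))
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  on <- which(r$values)
  dur <- r$lengths[on] * dt
  keep <- dur >= min_duration_s - 1e-9
  out <- data.frame(start_s = frame_times[starts[on][keep]],
                    end_s = frame_times[starts[on][keep]] + dur[keep],
                    duration_s = dur[keep])
  attr(out, "n_short_visits") <- sum(!keep)
  out
}

#' Latency to first arrival at the cool spot
#'
#' Time from trial start to the first on-spot frame. When the animal never
#' reaches the spot the trial duration is returned with the censoring flag
#' set.
#'
#' @param rec a `trial_recording`.
#' @return list with `latency_s` and logical `censored`.
#' @export
latency_first_arrival <- function(rec) {
  mask <- on_spot_mask(rec)
  t <- rec$trajectory$t
  if (!any(mask)) {
    return(list(latency_s = rec$trial_s, censored = TRUE))
  }
  list(latency_s = t[which(mask)[1]] - t[1], censored = FALSE)
}

#' Per-trial movement metrics
#'
#' The movement characteristics summarized per trial: total distance
#' travelled, time in rest (speed below `rest_speed_cms`), wall-following
#' time (within `wall_band_cm` of the perimeter), proportion of time on the
#' cool spot, latency and stay counts.
#'
#' @param rec a `trial_recording`.
#' @param rest_speed_cms speed threshold under which a frame counts as rest.
#' @param wall_band_cm perimeter-proximity band (about one body width).
#' @param min_stay_s,max_gap_s passed to [detect_stays()].
#' @return one-row data.frame with columns `animal_id`, `trial_index`,
#'   `condition`, `shape`, `latency_s`, `censored`, `prop_on_spot`,
#'   `distance_cm`, `rest_s`, `wall_follow_s`, `n_successful_stays`,
#'   `n_short_visits`.
#' @export
movement_metrics <- function(rec, rest_speed_cms = 0.5, wall_band_cm = 2.0,
                             min_stay_s = 5.0, max_gap_s = 0.2) {
  traj <- rec$trajectory
  n <- nrow(traj)
  dt <- frame_interval(traj)
  mask <- on_spot_mask(rec)
  stays <- detect_stays(mask, traj$t, min_stay_s, max_gap_s)
  lat <- latency_first_arrival(rec)
  seg <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
  spd <- if (n > 1) speed_series(traj) else 0
  wall <- distance_to_perimeter(rec$arena, cbind(traj$x, traj$y))
  data.frame(animal_id = rec$animal_id, trial_index = rec$trial_index,
             condition = rec$condition, shape = rec$arena$shape_kind,
             latency_s = lat$latency_s, censored = lat$censored,
             prop_on_spot = mean(mask),
             distance_cm = sum(seg),
             rest_s = sum(spd < rest_speed_cms) * dt,
             wall_follow_s = sum(wall <= wall_band_cm) * dt,
             n_successful_stays = nrow(stays),
             n_short_visits = attr(stays, "n_short_visits"),
             stringsAsFactors = FALSE)
}

#' Cumulative occupancy map
#'
#' Pools the frames of several recordings of one arena shape into a square
#' grid and reports the proportion of time spent in each cell; cells whose
#' centers fall outside the arena are masked with `NA`. Unmasked cells sum
#' to 1.
#'
#' @param recs list of `trial_recording`s sharing one arena shape.
#' @param bin_cm cell edge, cm.
#' @return list with `grid` (proportion matrix, rows = y bins bottom-up),
#'   `x_mid`, `y_mid` (cell centers) and `n_frames`.
#' @export
occupancy_map <- function(recs, bin_cm = 1.0) {
  if (inherits(recs, "trial_recording")) recs <- list(recs)
  if (!length(recs)) stop("occupancy_map needs at least one recording")
  shapes <- vapply(recs, function(r) r$arena$shape_kind, "")
  if (length(unique(shapes)) != 1L)
    stop("all recordings must share one arena shape")
  arena <- recs[[1]]$arena
  bb <- arena_bbox(arena)
  xb <- seq(bb[1, 1] - bin_cm / 2, bb[1, 2] + bin_cm, by = bin_cm)
  yb <- seq(bb[2, 1] - bin_cm / 2, bb[2, 2] + bin_cm, by = bin_cm)
  x <- unlist(lapply(recs, function(r) r$trajectory$x))
  y <- unlist(lapply(recs, function(r) r$trajectory$y))
  cx <- cut(x, xb, labels = FALSE, include.lowest = TRUE)
  cy <- cut(y, yb, labels = FALSE, include.lowest = TRUE)
  grid <- matrix(0, length(yb) - 1L, length(xb) - 1L)
  tab <- table(factor(cy, seq_len(nrow(grid))), factor(cx, seq_len(ncol(grid))))
  grid[] <- as.numeric(tab) / length(x)
  xm <- (xb[-1] + xb[-length(xb)]) / 2
  ym <- (yb[-1] + yb[-length(yb)]) / 2
  centers <- cbind(rep(xm, each = length(ym)), rep(ym, length(xm)))
  outside <- matrix(!arena_contains(arena, centers, tol = bin_cm / 2),
                    length(ym), length(xm))
  grid[outside & grid == 0] <- NA   # occupied boundary cells stay unmasked
  list(grid = grid, x_mid = xm, y_mid = ym, n_frames = length(x))
}

arena_bbox <- function(arena) {
  if (arena$shape_kind == "circle") {
    r <- arena$boundary$radius; ctr <- arena$boundary$center
    rbind(ctr[1] + c(-r, r), ctr[2] + c(-r, r))
  } else {
    rbind(range(arena$boundary[, 1]), range(arena$boundary[, 2]))
  }
}
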
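#' Extract approach paths preceding successful stays
#'
#' For every successful stay, the trajectory window covering the last
#' `window_s` seconds before the stay's first on-spot frame, i.e. frames
#' with `t` in `[start - window_s, start)`. Windows in which more than
#' `max_on_spot_frac` of the frames are already on the spot are excluded
#' (edge jitter around the spot rim, not a genuine approach), and windows
#' truncated by the trial start are dropped rather than padded.
#'
#' @param rec a `trial_recording`.
#' @param stays stays from [detect_stays()] on the same recording.
#' @param window_s approach-window length, seconds (default 3).
#' @param max_on_spot_frac exclusion threshold on the fraction of window
#'   frames already on-spot (default 0.95).
#' @return list of `approach_path` objects: each a list with `t`, `x`, `y`,
#'   `animal_id`, `trial_index`, `stay_index`, `shape`, `fps`.
#' @export
extract_approach_paths <- function(rec, stays, window_s = 3.0,
                                   max_on_spot_frac = 0.95) {
  traj <- rec$trajectory
  mask <- on_spot_mask(rec)
  out <- list()
  for (s in seq_len(nrow(stays))) {
    start <- stays$start_s[s]
    if (start - traj$t[1] < window_s - 1e-9) next  # truncated by trial start
    sel <- traj$t >= start - window_s & traj$t < start - 1e-12
    if (!any(sel)) next
    if (mean(mask[sel]) > max_on_spot_frac) next   # edge-jitter exclusion
    out[[length(out) + 1L]] <- structure(
      list(t = traj$t[sel], x = traj$x[sel], y = traj$y[sel],
           animal_id = rec$animal_id, trial_index = rec$trial_index,
           stay_index = s, shape = rec$arena$shape_kind,
           fps = attr(traj, "fps")),
      class = "approach_path")
  }
  out
}

#' Wall-distance series of an approach path
#'
#' The one-dimensional featurization clustered downstream: for every frame
#' of the approach path, the minimum Cartesian distance from the animal to
#' the arena perimeter, followed by per-series min-max scaling to [0, 1].
#'
#' @param path an `approach_path`.
#' @param arena the arena the path was recorded in.
#' @param scale `"per_series"` (default; each path scaled by its own
#'   extrema) or `"none"` (raw cm returned in `values` too).
#' @return an object of class `wall_distance_series`: list with `values`
#'   (scaled, unitless), `raw_values` (cm) and `length`.
#' @export
wall_distance_series <- function(path, arena,
                                 scale = c("per_series", "none")) {
  scale <- match.arg(scale)
  raw <- distance_to_perimeter(arena, cbind(path$x, path$y))
  vals <- if (scale == "per_series") minmax_scale(raw) else raw
  structure(list(values = vals, raw_values = raw, length = length(raw)),
            class = "wall_distance_series")
}

#' Min-max scaling to [0, 1]
#'
#' `(v - min) / (max - min)`; the minimum maps to 0 and the maximum to 1.
#' A constant series maps to all zeros: every value is pinned at its own
#' minimum, and this convention avoids a division by zero.
#'
#' @param v non-empty numeric vector.
#' @return scaled vector of the same length.
#' @export
minmax_scale <- function(v) {
  if (!length(v)) stop("cannot scale an empty series")
  rng <- range(v)
  if (rng[2] - rng[1] < 1e-300) return(rep(0, length(v)))
  (v - rng[1]) / (rng[2] - rng[1])
}

#' Tidy export of approach paths
#'
#' Long-format table, one row per frame of each approach path, with the raw
#' and scaled wall distances alongside the coordinates.
#'
#' @param paths list of `approach_path`s.
#' @param arena their arena.
#' @return data.frame with columns `animal_id`, `trial_index`, `stay_index`,
#'   `frame`, `t_s`, `x_cm`, `y_cm`, `wall_dist_cm`, `wall_dist_scaled`.
#' @export
approach_paths_table <- function(paths, arena) {
  rows <- lapply(paths, function(p) {
    w <- wall_distance_series(p, arena)
    data.frame(animal_id = p$animal_id, trial_index = p$trial_index,
               stay_index = p$stay_index, frame = seq_along(p$t) - 1L,
               t_s = p$t, x_cm = p$x, y_cm = p$y,
               wall_dist_cm = w$raw_values, wall_dist_scaled = w$values,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
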
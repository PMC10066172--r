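#' Strategy archetypes
#'
#' Names of the four approach-strategy archetypes the generator can emulate:
#' wall-following followed by a direct run to the spot, an inward spiral, a
#' sequence of arch-like ventures off the wall, and a center-out-and-return
#' excursion.
#' @export
archetype_names <- c("wall_then_direct", "spiral_inward", "arch_ventures",
                     "center_out_return")

# Kinematic parameters per archetype. The generator is a guided random walk
# in boundary-anchored coordinates: angular progress theta along the
# perimeter plus an "inwardness" coordinate u in [0, 1] (0 = on the wall,
# 1 = on the spot center), with a piecewise-linear target u-profile and
# smoothed noise on both coordinates. separation = "zero" collapses all
# archetypes onto one common parameter set (a pure inward ramp), a null
# configuration for clustering benchmarks.
archetype_params <- function(name, separation = c("high", "zero")) {
  separation <- match.arg(separation)
  name <- match.arg(name, archetype_names)
  if (separation == "zero") {
    return(list(name = name, pin_start = FALSE,
                keys = cbind(s = c(0, 1), u = c(0.05, 1)),
                omega = 1.2, u_noise = 0.02, theta_noise = 0.08))
  }
  switch(name,
    wall_then_direct = list(
      name = name, pin_start = FALSE,
      keys = cbind(s = c(0, 0.7, 1), u = c(0.03, 0.03, 1)),
      omega = 1.5, u_noise = 0.010, theta_noise = 0.08),
    spiral_inward = list(
      name = name, pin_start = FALSE,
      keys = cbind(s = c(0, 1), u = c(0.05, 1)),
      omega = 2.2, u_noise = 0.010, theta_noise = 0.08),
    arch_ventures = list(
      name = name, pin_start = FALSE,
      keys = cbind(s = c(0, 0.2, 0.4, 0.6, 0.75, 1),
                   u = c(0.08, 0.5, 0.08, 0.5, 0.08, 1)),
      omega = 1.0, u_noise = 0.015, theta_noise = 0.08),
    center_out_return = list(
      name = name, pin_start = TRUE,
      keys = cbind(s = c(0, 0.45, 1), u = c(1, 0.12, 1)),
      omega = 0.8, u_noise = 0.015, theta_noise = 0.08))
}

# Boundary point in direction theta from the spot center (the arenas are
# convex and the spot is interior, so the ray meets the boundary once).
boundary_point <- function(arena, theta) {
  if (arena$shape_kind == "circle") {
    r <- arena$boundary$radius
    ctr <- arena$boundary$center
    return(cbind(ctr[1] + r * cos(theta), ctr[2] + r * sin(theta)))
  }
  v <- arena$boundary
  j <- c(seq_len(nrow(v))[-1], 1L)
  dx <- cos(theta); dy <- sin(theta)
  tmin <- rep(Inf, length(theta))
  for (e in seq_len(nrow(v))) {
    a <- v[e, ]; ee <- v[j[e], ] - a
    den <- dx * ee[2] - dy * ee[1]          # cross(d, e)
    tt <- (a[1] * ee[2] - a[2] * ee[1]) / den
    ss <- (dx * a[2] - dy * a[1]) / den * -1
    ok <- is.finite(tt) & tt > 1e-9 & ss >= -1e-9 & ss <= 1 + 1e-9
    tmin <- ifelse(ok & tt < tmin, tt, tmin)
  }
  cbind(dx * tmin, dy * tmin)
}

# Position from boundary-anchored coordinates: convex combination of the
# boundary point at theta and the spot center, which stays inside a convex
# arena for any u in [0, 1].
pos_from_tu <- function(arena, theta, u) {
  b <- boundary_point(arena, theta)
  ctr <- arena$spot_center
  cbind(ctr[1] + (1 - u) * (b[, 1] - ctr[1]),
        ctr[2] + (1 - u) * (b[, 2] - ctr[2]))
}

# Moving-average smoothed Gaussian noise with stationary sd ~ sd.
smooth_noise <- function(n, sd, width = 7L) {
  if (n == 0 || sd == 0) return(numeric(n))
  w <- min(width, max(1L, n))
  z <- stats::filter(stats::rnorm(n + w, sd = sd), rep(1, w) / w,
                     sides = 1)
  as.numeric(z[(w + 1):(w + n)]) * sqrt(w)
}

piecewise_u <- function(keys, n) {
  stats::approx(keys[, "s"], keys[, "u"], xout = seq(0, 1, length.out = n))$y
}

# Pull any stray points back inside by reflecting across the nearest
# boundary; fall back to a small inward pull if a point is still outside.
reflect_into_arena <- function(arena, pts) {
  bad <- which(!arena_contains(arena, pts))
  for (i in bad) {
    p <- pts[i, ]
    if (arena$shape_kind == "circle") {
      ctr <- arena$boundary$center; r <- arena$boundary$radius
      rad <- sqrt(sum((p - ctr)^2))
      pts[i, ] <- ctr + (p - ctr) * (2 * r - rad) / rad
    } else {
      q <- nearest_boundary_point(arena, p)
      pts[i, ] <- 2 * q - p
    }
    if (!arena_contains(arena, pts[i, , drop = FALSE])) {
      q <- nearest_boundary_point(arena, p)
      ctr <- arena$spot_center
      pts[i, ] <- q + 0.02 * (ctr - q)
    }
  }
  pts
}

nearest_boundary_point <- function(arena, p) {
  if (arena$shape_kind == "circle") {
    ctr <- arena$boundary$center
    d <- p - ctr
    return(ctr + d / sqrt(sum(d^2)) * arena$boundary$radius)
  }
  v <- arena$boundary
  j <- c(seq_len(nrow(v))[-1], 1L)
  best <- NULL; bestd <- Inf
  for (e in seq_len(nrow(v))) {
    a <- v[e, ]; b <- v[j[e], ]
    ab <- b - a
    t <- sum((p - a) * ab) / sum(ab^2)
    t <- min(1, max(0, t))
    q <- a + t * ab
    d <- sum((p - q)^2)
    if (d < bestd) { bestd <- d; best <- q }
  }
  best
}

#' Generate one strategy-archetype path
#'
#' Simulates a single approach of the named strategy inside an arena as a
#' guided random walk in boundary-anchored coordinates (angular progress
#' along the perimeter plus a noisy piecewise-linear inwardness profile
#' between wall and spot). `wall_then_direct` hugs the wall band and then
#' runs straight to the spot; `spiral_inward` ramps inward while circling;
#' `arch_ventures` repeatedly leaves and rejoins the wall band before the
#' final inward run; `center_out_return` starts on the spot, ventures
#' toward the wall and returns. Construction keeps every point inside the
#' arena. Identical seeds give bit-identical output.
#'
#' @param archetype one of [archetype_names].
#' @param arena the arena to generate in.
#' @param duration_s path duration, seconds (default the 3-s approach
#'   window).
#' @param fps frame rate.
#' @param seed optional integer seed.
#' @param separation `"high"` (distinct archetype kinematics) or `"zero"`
#'   (all archetypes share one parameter set; a clustering null).
#' @param theta0 starting angular position, radians (random if `NULL`).
#' @param t0 time stamp of the first frame.
#' @return list with `trajectory` (a [trajectory()]) and `label` (the
#'   archetype name).
#' @export
gen_strategy_path <- function(archetype, arena, duration_s = 3.0, fps = 30,
                              seed = NULL, separation = "high",
                              theta0 = NULL, t0 = 0) {
  if (!is.null(seed)) set.seed(seed)
  par <- archetype_params(archetype, separation)
  n <- max(2L, round(duration_s * fps))
  dt <- 1 / fps
  if (is.null(theta0)) theta0 <- stats::runif(1, 0, 2 * pi)
  theta <- theta0 + cumsum(rep(par$omega * dt, n)) +
    smooth_noise(n, par$theta_noise * sqrt(dt))
  u <- piecewise_u(par$keys, n) + smooth_noise(n, par$u_noise)
  u <- pmin(1, pmax(0, u))
  # pin the terminal contact: approaches end on the spot, and
  # center-out-return also starts there
  u[n] <- max(u[n], 0.97)
  if (par$pin_start) u[1] <- max(u[1], 0.97)
  xy <- pos_from_tu(arena, theta, u)
  xy <- reflect_into_arena(arena, xy)
  list(trajectory = trajectory(t0 + (seq_len(n) - 1L) * dt,
                               xy[, 1], xy[, 2], fps = fps),
       label = par$name)
}

#' Session configuration for the synthetic generator
#'
#' The defaults are the study conditions of the paradigm: 15 animals per
#' arena shape, 10 trials of 300 s each, 30 fps, and learning trends on the
#' transformed scales whose magnitudes match the reported circle-arena
#' estimates (sqrt-proportion slope 0.026 per trial, log-latency slope
#' -0.185 per trial).
#'
#' @param shape arena shape name.
#' @param n_animals animals in the session.
#' @param n_trials trials per animal (1..10).
#' @param trial_s trial duration, seconds.
#' @param fps frame rate.
#' @param latency_log_intercept mean log(latency + 1) at trial 1.
#' @param latency_log_slope per-trial change of log-latency.
#' @param prop_sqrt_intercept mean sqrt(on-spot proportion) at trial 1.
#' @param prop_sqrt_slope per-trial change of sqrt-proportion.
#' @param animal_sd between-animal sd of the transformed intercepts.
#' @param noise_sd residual sd on the transformed scales.
#' @param archetype_weights mixture weights of the first-approach
#'   archetypes (re-approaches after a stay are center-out-return by
#'   construction); must sum to 1.
#' @param condition `"heated"`, `"unheated"` or `"blinded"`; unheated
#'   control sessions have no cool spot and produce free wandering.
#' @param seed session seed.
#' @return object of class `session_config`.
#' @export
session_config <- function(shape = "circle", n_animals = 15, n_trials = 10,
                           trial_s = 300, fps = 30,
                           latency_log_intercept = log(120),
                           latency_log_slope = -0.185,
                           prop_sqrt_intercept = 0.22,
                           prop_sqrt_slope = 0.026,
                           animal_sd = 0.08, noise_sd = 0.05,
                           archetype_weights = c(wall_then_direct = 0.55,
                                                 spiral_inward = 0.30,
                                                 arch_ventures = 0.15),
                           condition = "heated", seed = 1L) {
  condition <- match.arg(condition, c("heated", "unheated", "blinded"))
  if (n_animals < 1 || n_trials < 1 || n_trials > 10 || trial_s <= 0 ||
      fps <= 0)
    stop("counts and durations must be positive (n_trials at most 10)")
  if (abs(sum(archetype_weights) - 1) > 1e-9)
    stop("archetype weights must sum to 1")
  if (!all(names(archetype_weights) %in% archetype_names))
    stop("unknown archetype in weights; valid: ",
         paste(archetype_names, collapse = ", "))
  structure(as.list(environment()), class = "session_config")
}

# One heated trial: wall-band search until the target latency, a labeled
# 3-s approach, then stays on the spot alternating with center-out-return
# excursions; any remaining tail is spent wandering off-spot.
gen_trial <- function(cfg, arena, latency_target, prop_target, rng_theta) {
  fps <- cfg$fps; dt <- 1 / fps
  n_total <- round(cfg$trial_s * fps)
  approach_s <- 3.0
  L <- min(max(latency_target, approach_s + 1), cfg$trial_s - 15)
  T_on <- min(prop_target * cfg$trial_s, cfg$trial_s - L - 8)
  T_on <- max(T_on, 6)
  n_stays <- 1L + (T_on > 60) + (T_on > 120)
  gap_s <- 8
  while (n_stays > 1 &&
         L + T_on + (n_stays - 1) * (gap_s + approach_s) > cfg$trial_s - 2)
    n_stays <- n_stays - 1L
  stay_s <- rep(T_on / n_stays, n_stays)

  first_arch <- sample(names(cfg$archetype_weights), 1,
                       prob = cfg$archetype_weights)
  archetypes <- c(first_arch, rep("center_out_return", n_stays - 1L))

  theta <- rng_theta
  segs <- list(); labels <- character(0)
  add_seg <- function(xy) segs[[length(segs) + 1L]] <<- xy

  # search: wall-band wander
  n_search <- max(0L, round((L - approach_s) * fps))
  if (n_search > 0) {
    th <- theta + cumsum(rep(0.9 * dt, n_search)) +
      smooth_noise(n_search, 0.15 * sqrt(dt))
    u <- pmin(0.35, pmax(0.01, 0.06 + smooth_noise(n_search, 0.05)))
    add_seg(pos_from_tu(arena, th, u))
    theta <- th[n_search]
  }
  for (s in seq_len(n_stays)) {
    ap <- gen_strategy_path(archetypes[s], arena, approach_s, fps,
                            theta0 = theta, separation = "high")
    add_seg(cbind(ap$trajectory$x, ap$trajectory$y))
    theta <- theta + archetype_params(archetypes[s])$omega * approach_s
    n_stay <- max(round(stay_s[s] * fps), round(5.5 * fps))
    jit <- cbind(smooth_noise(n_stay, 0.35), smooth_noise(n_stay, 0.35))
    rad <- sqrt(rowSums(jit^2))
    over <- rad > 0.85 * arena$spot_radius
    jit[over, ] <- jit[over, ] * (0.85 * arena$spot_radius / rad[over])
    add_seg(sweep(jit, 2, arena$spot_center, "+"))
    if (s < n_stays) {   # excursion out and back; its tail is a re-approach
      ex <- gen_strategy_path("center_out_return", arena, gap_s, fps,
                              theta0 = theta, separation = "high")
      nex <- nrow(ex$trajectory)
      add_seg(cbind(ex$trajectory$x, ex$trajectory$y)[-nex, , drop = FALSE])
      theta <- theta + archetype_params("center_out_return")$omega * gap_s
    }
  }
  xy <- do.call(rbind, segs)
  # tail: leave the spot and wander near the wall for the rest of the trial
  n_tail <- n_total - nrow(xy)
  if (n_tail > 0) {
    n_leave <- min(n_tail, round(2 * fps))
    u_leave <- seq(0.97, 0.25, length.out = n_leave)
    th <- theta + cumsum(rep(0.8 * dt, n_tail)) +
      smooth_noise(n_tail, 0.12 * sqrt(dt))
    u_w <- pmin(0.35, pmax(0.01, 0.06 + smooth_noise(n_tail, 0.05)))
    u <- c(u_leave, u_w[seq_len(n_tail - n_leave)])
    xy <- rbind(xy, pos_from_tu(arena, th, u))
  } else if (n_tail < 0) {
    xy <- xy[seq_len(n_total), , drop = FALSE]
  }
  xy <- reflect_into_arena(arena, xy)
  list(traj = trajectory((seq_len(n_total) - 1L) * dt, xy[, 1], xy[, 2],
                         fps = fps),
       archetypes = archetypes, n_stays = n_stays)
}

# Control trial without a cool spot: free wander over the whole floor.
gen_control_trial <- function(cfg, arena, rng_theta) {
  fps <- cfg$fps; dt <- 1 / fps
  n <- round(cfg$trial_s * fps)
  th <- rng_theta + cumsum(rep(0.7 * dt, n)) + smooth_noise(n, 0.2 * sqrt(dt))
  u <- pmin(0.9, pmax(0.01, 0.12 + smooth_noise(n, 0.12)))
  xy <- reflect_into_arena(arena, pos_from_tu(arena, th, u))
  list(traj = trajectory((seq_len(n) - 1L) * dt, xy[, 1], xy[, 2], fps = fps),
       archetypes = character(0), n_stays = 0L)
}

# The synthetic camera frame all session files are written in: 10 px/cm,
# slightly rotated, y-down, offset sensor origin.
session_calibration <- function() {
  structure(list(scale = 0.1, rotation = 0.05, flip = TRUE,
                 translation = c(-30, -25), rms_residual = 0),
            class = "calibration")
}

#' Generate a synthetic session on disk
#'
#' Writes one tracking CSV per animal x trial in the canonical dialect
#' (pixel coordinates under a fixed synthetic camera calibration, landmark
#' columns included) under `out_dir/<shape>/<animal>/trial_<j>.csv`, plus a
#' `truth.json` recording the seed, the configured transformed-scale
#' trends, and per trial the intended latency, intended on-spot proportion
#' and the archetype of every approach.
#'
#' @param cfg a [session_config()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, the truth list.
#' @export
gen_session <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "session_config"))
  arena <- build_arena(cfg$shape)
  cal <- session_calibration()
  shape_dir <- file.path(out_dir, cfg$shape)
  set.seed(cfg$seed)
  truth <- list(seed = cfg$seed, shape = cfg$shape,
                condition = cfg$condition,
                latency_log_slope = cfg$latency_log_slope,
                prop_sqrt_slope = cfg$prop_sqrt_slope,
                fps = cfg$fps, trial_s = cfg$trial_s, trials = list())
  has_spot <- cfg$condition == "heated" || cfg$condition == "blinded"
  for (i in seq_len(cfg$n_animals)) {
    aid <- sprintf("animal%02d", i)
    dir.create(file.path(shape_dir, aid), recursive = TRUE,
               showWarnings = FALSE)
    b_lat <- stats::rnorm(1, 0, cfg$animal_sd)
    b_prop <- stats::rnorm(1, 0, cfg$animal_sd)
    for (j in seq_len(cfg$n_trials)) {
      lat_t <- exp(cfg$latency_log_intercept + b_lat +
                     cfg$latency_log_slope * (j - 1) +
                     stats::rnorm(1, 0, cfg$noise_sd)) - 1
      q <- cfg$prop_sqrt_intercept + b_prop +
        cfg$prop_sqrt_slope * (j - 1) + stats::rnorm(1, 0, cfg$noise_sd)
      prop_t <- min(0.9, max(0.02, q))^2
      tr <- if (has_spot)
        gen_trial(cfg, arena, lat_t, prop_t, stats::runif(1, 0, 2 * pi))
      else gen_control_trial(cfg, arena, stats::runif(1, 0, 2 * pi))
      rec <- trial_recording(tr$traj, arena, animal_id = aid,
                             trial_index = j, condition = cfg$condition,
                             trial_s = cfg$trial_s)
      write_tracking_table(rec, file.path(shape_dir, aid,
                                          sprintf("trial_%02d.csv", j)),
                           calibration = cal)
      truth$trials[[length(truth$trials) + 1L]] <-
        list(animal_id = aid, trial_index = j,
             latency_target_s = if (has_spot) lat_t else cfg$trial_s,
             prop_target = if (has_spot) prop_t else NA,
             archetypes = tr$archetypes, n_stays = tr$n_stays)
    }
  }
  jsonlite::write_json(truth, file.path(shape_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(truth)
}

#' Generate a metrics-level synthetic session
#'
#' Draws per-trial responses directly on the transformed scales --
#' `sqrt(prop) = intercept + slope * (trial - 1) + animal effect + noise`
#' and likewise for `log(latency + 1)` -- and back-transforms them into a
#' tidy metrics table. This is the statistical model the slope estimator
#' targets, without the trajectory layer, so large replicate studies of
#' estimator calibration stay cheap.
#'
#' @inheritParams session_config
#' @param animal_slope_sd between-animal sd of the per-trial slopes
#'   (sqrt scale; the log-latency slope sd is `3 * animal_slope_sd`).
#' @param seed integer seed.
#' @return data.frame with columns `animal_id`, `trial_index`,
#'   `prop_on_spot`, `latency_s`, `censored`, `shape`, `condition`.
#' @export
gen_metrics_session <- function(shape = "circle", n_animals = 15,
                                n_trials = 10, trial_s = 300,
                                latency_log_intercept = log(120),
                                latency_log_slope = -0.185,
                                prop_sqrt_intercept = 0.22,
                                prop_sqrt_slope = 0.026,
                                animal_sd = 0.08, animal_slope_sd = 0.008,
                                noise_sd = 0.05, seed = 1L) {
  set.seed(seed)
  rows <- vector("list", n_animals)
  for (i in seq_len(n_animals)) {
    b0p <- stats::rnorm(1, 0, animal_sd)
    b0l <- stats::rnorm(1, 0, animal_sd)
    b1p <- stats::rnorm(1, 0, animal_slope_sd)
    b1l <- stats::rnorm(1, 0, 3 * animal_slope_sd)
    j <- seq_len(n_trials)
    q <- prop_sqrt_intercept + b0p + (prop_sqrt_slope + b1p) * (j - 1) +
      stats::rnorm(n_trials, 0, noise_sd)
    lat <- exp(latency_log_intercept + b0l +
                 (latency_log_slope + b1l) * (j - 1) +
                 stats::rnorm(n_trials, 0, noise_sd)) - 1
    rows[[i]] <- data.frame(animal_id = sprintf("animal%02d", i),
                            trial_index = j,
                            prop_on_spot = pmin(1, pmax(0, q))^2,
                            latency_s = pmin(trial_s, pmax(0, lat)),
                            censored = lat >= trial_s,
                            shape = shape, condition = "heated",
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Labeled approach-path benchmark for clustering
#'
#' Balanced set of 3-s approach windows drawn from the four strategy
#' archetypes at the requested separation, with truth labels, for
#' validating the DTW + PAM stage.
#'
#' @param n_per_archetype windows per archetype (default 40).
#' @param arena the arena (default the circle).
#' @param separation `"high"` or `"zero"` (see [gen_strategy_path()]).
#' @param seed integer seed.
#' @param fps frame rate.
#' @return list with `paths` (list of `approach_path`s), `labels` (integer
#'   1..4 truth), `label_names`, `arena`.
#' @export
gen_cluster_benchmark <- function(n_per_archetype = 40, arena = NULL,
                                  separation = "high", seed = 1L, fps = 30) {
  if (is.null(arena)) arena <- build_arena("circle")
  if (n_per_archetype * 4 < 4) stop("need at least one path per archetype")
  set.seed(seed)
  paths <- list(); labels <- integer(0)
  for (k in seq_along(archetype_names)) {
    for (r in seq_len(n_per_archetype)) {
      g <- gen_strategy_path(archetype_names[k], arena, 3.0, fps,
                             separation = separation)
      paths[[length(paths) + 1L]] <- structure(
        list(t = g$trajectory$t, x = g$trajectory$x, y = g$trajectory$y,
             animal_id = sprintf("bench%03d", length(paths) + 1L),
             trial_index = 1L, stay_index = 1L, shape = arena$shape_kind,
             fps = fps),
        class = "approach_path")
      labels <- c(labels, k)
    }
  }
  list(paths = paths, labels = labels, label_names = archetype_names,
       arena = arena)
}
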
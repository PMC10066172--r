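#' Pipeline configuration
#'
#' Resolved thresholds and knobs of the full analysis, serialized verbatim
#' into every output directory. Defaults are the paradigm's stated rules
#' (5-s stay, 3-s approach window, 95% on-spot exclusion, k = 4) and this
#' package's documented conventions (0.5 cm/s rest speed, 2 cm wall band,
#' symmetric2 DTW).
#'
#' @param stay_s minimum successful-stay duration, seconds.
#' @param stay_gap_s bridged on-spot interruption, seconds.
#' @param window_s approach-window length, seconds.
#' @param max_on_spot_frac approach-window on-spot exclusion threshold.
#' @param rest_speed_cms rest-speed threshold, cm/s.
#' @param wall_band_cm wall-following band, cm.
#' @param dtw a [dtw_config()]. The pipeline default constrains warping to
#'   a 1-s (30-frame) Sakoe-Chiba band: unconstrained DTW warps away all
#'   timing information, collapsing monotone approach profiles
#'   (wall-hugging-then-direct vs gradual inward) to noise-level distance,
#'   whereas a band retains the wall-dwell signal that separates them.
#' @param k cluster count; `k_scan` must contain it.
#' @param k_scan candidate k range for the silhouette scan.
#' @param log_offset_s latency log-transform offset, seconds.
#' @param seed pipeline seed (recorded; tie-breaking is deterministic).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(stay_s = 5.0, stay_gap_s = 0.2, window_s = 3.0,
                            max_on_spot_frac = 0.95, rest_speed_cms = 0.5,
                            wall_band_cm = 2.0,
                            dtw = dtw_config(window = 30L),
                            k = 4, k_scan = 2:8, log_offset_s = 1,
                            seed = 1L) {
  vals <- c(stay_s, stay_gap_s, window_s, max_on_spot_frac, rest_speed_cms,
            wall_band_cm, log_offset_s)
  if (any(vals <= 0)) stop("every threshold must be positive")
  if (!k %in% k_scan) stop("k_scan must contain k")
  structure(list(stay_s = stay_s, stay_gap_s = stay_gap_s,
                 window_s = window_s, max_on_spot_frac = max_on_spot_frac,
                 rest_speed_cms = rest_speed_cms,
                 wall_band_cm = wall_band_cm, dtw = dtw, k = k,
                 k_scan = k_scan, log_offset_s = log_offset_s, seed = seed),
            class = "pipeline_config")
}

config_as_list <- function(cfg) {
  out <- unclass(cfg)
  out$dtw <- unclass(out$dtw)
  out$version <- as.character(utils::packageVersion("coolspot"))
  out
}

#' Simulate a session to disk
#'
#' Thin orchestration over [gen_session()]: generates the session tree,
#' writes the resolved configuration next to it and prints a file count and
#' truth summary.
#'
#' @param cfg a [session_config()].
#' @param out_dir output directory.
#' @param quiet suppress the summary message.
#' @return invisibly, the session directory.
#' @export
run_simulate <- function(cfg, out_dir, quiet = FALSE) {
  truth <- gen_session(cfg, out_dir)
  files <- list.files(file.path(out_dir, cfg$shape), recursive = TRUE,
                      pattern = "^trial_.*\\.csv$")
  jsonlite::write_json(list(session = unclass(cfg),
                            version = as.character(
                              utils::packageVersion("coolspot"))),
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!quiet)
    message(sprintf("simulated %d trials (%s, %d animals, condition %s)",
                    length(files), cfg$shape, cfg$n_animals, cfg$condition))
  invisible(out_dir)
}

#' Load a session directory into trial recordings
#'
#' Reads every `trial_*.csv` under `session_dir/<shape>/<animal>/`,
#' calibrating each file from its landmark columns (or accepting the
#' pre-calibrated 3-column dialect).
#'
#' @param session_dir session root written by [run_simulate()].
#' @param fps nominal frame rate.
#' @param trial_s nominal trial duration, seconds.
#' @return list of `trial_recording`s.
#' @export
load_session <- function(session_dir, fps = 30, trial_s = 300) {
  shapes <- intersect(list.dirs(session_dir, recursive = FALSE,
                                full.names = FALSE),
                      c("circle", "square", "triangle", "quadrilateral"))
  if (!length(shapes)) stop("no arena-shape directories under ", session_dir)
  recs <- list()
  for (shape in shapes) {
    arena <- build_arena(shape)
    truth_path <- file.path(session_dir, shape, "truth.json")
    cond <- if (file.exists(truth_path))
      jsonlite::read_json(truth_path)$condition else "heated"
    for (adir in list.dirs(file.path(session_dir, shape),
                           recursive = FALSE)) {
      for (f in list.files(adir, pattern = "^trial_.*\\.csv$",
                           full.names = TRUE)) {
        j <- as.integer(sub("^trial_0*([0-9]+)\\.csv$", "\\1", basename(f)))
        recs[[length(recs) + 1L]] <-
          read_tracking_table(f, arena, fps = fps,
                              animal_id = basename(adir), trial_index = j,
                              condition = cond, trial_s = trial_s)
      }
    }
  }
  if (!length(recs)) stop("session ", session_dir, " contains no trials")
  recs
}

#' Analyze a session: metrics, learning slopes, occupancy
#'
#' Runs calibration, per-trial metrics, response transforms and the
#' two-stage slope estimator for every arena shape present, and writes
#' `metrics.csv`, `slopes.json`, one `occupancy_<shape>.csv` per shape and
#' the resolved `config.json` into `out_dir`.
#'
#' @param session_dir session root (or a pre-loaded recording list).
#' @param out_dir output directory.
#' @param cfg a [pipeline_config()].
#' @param fps,trial_s passed to [load_session()].
#' @param quiet suppress log messages.
#' @return invisibly, a list with `metrics` (data.frame) and `slopes`.
#' @export
run_analyze <- function(session_dir, out_dir, cfg = pipeline_config(),
                        fps = 30, trial_s = 300, quiet = FALSE) {
  recs <- if (is.list(session_dir) && !is.character(session_dir))
    session_dir else load_session(session_dir, fps = fps, trial_s = trial_s)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  metrics <- do.call(rbind, lapply(recs, movement_metrics,
                                   rest_speed_cms = cfg$rest_speed_cms,
                                   wall_band_cm = cfg$wall_band_cm,
                                   min_stay_s = cfg$stay_s,
                                   max_gap_s = cfg$stay_gap_s))
  utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE, quote = FALSE)
  slopes <- list()
  for (shape in unique(metrics$shape)) {
    m <- metrics[metrics$shape == shape, ]
    if (length(unique(m$animal_id)) < 2 || max(m$trial_index) < 3) next
    sp <- estimate_learning_slope(m, "prop_on_spot", "sqrt",
                                  seed = cfg$seed)
    sl <- estimate_learning_slope(m, "latency_s", "log",
                                  offset = cfg$log_offset_s, seed = cfg$seed)
    slopes[[shape]] <- list(
      prop_on_spot_sqrt = unclass(sp)[c("slope", "se", "ci95", "ci95_boot",
                                        "n_animals")],
      latency_log = unclass(sl)[c("slope", "se", "ci95", "ci95_boot",
                                  "n_animals")])
  }
  jsonlite::write_json(list(slopes = slopes,
                            n_censored = sum(metrics$censored),
                            config = config_as_list(cfg)),
                       file.path(out_dir, "slopes.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (shape in unique(metrics$shape)) {
    shape_recs <- recs[vapply(recs, function(r) r$arena$shape_kind, "")
                       == shape]
    occ <- occupancy_map(shape_recs)
    grid <- occ$grid
    dimnames(grid) <- list(y_cm = sprintf("%.1f", occ$y_mid),
                           x_cm = sprintf("%.1f", occ$x_mid))
    utils::write.csv(grid, file.path(out_dir,
                                     sprintf("occupancy_%s.csv", shape)))
  }
  jsonlite::write_json(config_as_list(cfg),
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!quiet)
    message(sprintf("analyzed %d trials (%d censored latencies)",
                    nrow(metrics), sum(metrics$censored)))
  invisible(list(metrics = metrics, slopes = slopes))
}

#' Cluster approach paths of a session
#'
#' Extracts every approach path preceding a successful stay, featurizes
#' each into a scaled wall-distance series, computes the pairwise DTW
#' matrix, runs PAM at `cfg$k` and across `cfg$k_scan`, and tabulates
#' clusters by arena shape. Writes `clusters.csv` (one row per approach),
#' `medoids.csv` (medoid trajectories), `validity.json` (silhouette scan,
#' counts, config).
#'
#' @inheritParams run_analyze
#' @return invisibly, a list with `result` (the `clustering_result`),
#'   `paths`, `scan` (silhouette per k), `counts`.
#' @export
run_cluster <- function(session_dir, out_dir, cfg = pipeline_config(),
                        fps = 30, trial_s = 300, quiet = FALSE) {
  recs <- if (is.list(session_dir) && !is.character(session_dir))
    session_dir else load_session(session_dir, fps = fps, trial_s = trial_s)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(); arenas <- list()
  for (r in recs) {
    stays <- detect_stays(on_spot_mask(r), r$trajectory$t,
                          cfg$stay_s, cfg$stay_gap_s)
    ap <- extract_approach_paths(r, stays, cfg$window_s,
                                 cfg$max_on_spot_frac)
    paths <- c(paths, ap)
    arenas[[r$arena$shape_kind]] <- r$arena
  }
  if (length(paths) < cfg$k)
    stop(sprintf("only %d approach paths extracted; k = %d needs at least k",
                 length(paths), cfg$k))
  series <- lapply(paths, function(p)
    wall_distance_series(p, arenas[[p$shape]]))
  D <- dtw_matrix(series, cfg$dtw)
  res <- pam_cluster(D, k = cfg$k, seed = cfg$seed)
  scan <- scan_k(D, intersect(cfg$k_scan, 2:(length(paths) - 1)),
                 seed = cfg$seed)
  shapes <- vapply(paths, function(p) p$shape, "")
  counts <- cluster_counts(res, shapes)
  tab <- data.frame(animal_id = vapply(paths, `[[`, "", "animal_id"),
                    trial_index = vapply(paths, `[[`, 0L, "trial_index"),
                    stay_index = vapply(paths, `[[`, 0L, "stay_index"),
                    shape = shapes, cluster = res$labels)
  utils::write.csv(tab, file.path(out_dir, "clusters.csv"),
                   row.names = FALSE, quote = FALSE)
  med <- do.call(rbind, lapply(seq_along(res$medoid_indices), function(ci) {
    p <- paths[[res$medoid_indices[ci]]]
    data.frame(cluster = ci, t_s = p$t, x_cm = p$x, y_cm = p$y)
  }))
  utils::write.csv(med, file.path(out_dir, "medoids.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(k = cfg$k, silhouette_scan = scan,
         silhouette_at_k = res$validity$silhouette_mean,
         counts = as.data.frame(counts$counts),
         modal_cluster = as.list(counts$modal_cluster),
         config = config_as_list(cfg)),
    file.path(out_dir, "validity.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!quiet)
    message(sprintf("clustered %d approach paths at k = %d (mean silhouette %.3f)",
                    length(paths), cfg$k, res$validity$silhouette_mean))
  invisible(list(result = res, paths = paths, scan = scan,
                 counts = counts))
}
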
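#' DTW configuration
#'
#' Knobs of the dynamic-time-warping distance. `symmetric2` (the common
#' default of DTW packages) weights the diagonal step with twice the local
#' cost; `symmetric1` weights all three steps equally. An optional
#' Sakoe-Chiba band restricts warping to `|i - j| <= window` frames, and
#' `normalize = "path_length"` divides the symmetric2 distance by
#' `length(a) + length(b)`.
#'
#' @param step_pattern `"symmetric2"` (default) or `"symmetric1"`.
#' @param window optional band half-width in frames (`NULL` = unconstrained).
#' @param normalize `"none"` (default) or `"path_length"`.
#' @return an object of class `dtw_config`.
#' @export
dtw_config <- function(step_pattern = c("symmetric2", "symmetric1"),
                       window = NULL, normalize = c("none", "path_length")) {
  step_pattern <- match.arg(step_pattern)
  normalize <- match.arg(normalize)
  if (!is.null(window) && (window < 0 || window != round(window)))
    stop("window must be a non-negative whole number of frames")
  structure(list(step_pattern = step_pattern, window = window,
                 normalize = normalize),
            class = "dtw_config")
}

series_values <- function(s) {
  if (inherits(s, "wall_distance_series")) s$values else as.numeric(s)
}

#' DTW distance between two series
#'
#' Minimum cumulative `|a_i - b_j|` cost over monotone warping paths, by
#' dynamic programming with the configured step weights. Symmetric in its
#' arguments and zero for identical series.
#'
#' @param a,b non-empty numeric vectors (or `wall_distance_series`).
#' @param cfg a [dtw_config()].
#' @return the DTW distance.
#' @export
dtw_distance <- function(a, b, cfg = dtw_config()) {
  a <- series_values(a); b <- series_values(b)
  if (!length(a) || !length(b)) stop("DTW requires non-empty series")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("DTW requires finite values")
  win <- if (is.null(cfg$window)) -1L else as.integer(cfg$window)
  if (win >= 0 && win < abs(length(a) - length(b)))
    stop(sprintf("window %d infeasible for lengths %d and %d",
                 win, length(a), length(b)))
  step <- if (cfg$step_pattern == "symmetric1") 1L else 2L
  d <- dtw_distance_cpp(a, b, step, win)
  if (cfg$normalize == "path_length") d / (length(a) + length(b)) else d
}

#' Pairwise DTW distance matrix
#'
#' All pairwise [dtw_distance()] values, each unordered pair computed once;
#' symmetric with zero diagonal.
#'
#' @param series_list list of at least 2 series.
#' @param cfg a [dtw_config()].
#' @return an n x n numeric matrix.
#' @export
dtw_matrix <- function(series_list, cfg = dtw_config()) {
  if (length(series_list) < 2) stop("need at least 2 series")
  vals <- lapply(series_list, series_values)
  lens <- lengths(vals)
  if (any(lens == 0)) stop("DTW requires non-empty series")
  if (any(!vapply(vals, function(v) all(is.finite(v)), TRUE)))
    stop("DTW requires finite values")
  win <- if (is.null(cfg$window)) -1L else as.integer(cfg$window)
  if (win >= 0 && win < max(lens) - min(lens))
    stop("window infeasible for the range of series lengths")
  step <- if (cfg$step_pattern == "symmetric1") 1L else 2L
  D <- dtw_matrix_cpp(vals, step, win)
  if (cfg$normalize == "path_length") {
    norm <- outer(lens, lens, "+")
    diag(norm) <- 1
    D <- D / norm
  }
  D
}
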
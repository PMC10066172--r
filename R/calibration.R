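#' Landmark-based similarity calibration
#'
#' Least-squares similarity transform (uniform scale + rotation +
#' translation, optionally mirrored) mapping the four tracked pixel
#' landmarks onto the arena's canonical landmarks. Video trackers report the
#' corners in an arbitrary starting corner and traversal direction, and
#' image coordinate frames are routinely y-down, so the landmark-to-corner
#' correspondence is resolved by trying all four cyclic orders in both
#' traversal directions and keeping the fit with minimum RMS residual; a
#' mirrored frame is absorbed by a reflection flag.
#'
#' @param tracked_px 4 x 2 matrix of landmark positions in pixels.
#' @param arena the arena whose [arena_landmarks()] are the targets.
#' @param max_rms_cm calibration fails if the best residual exceeds this.
#' @return an object of class `calibration`: `scale` (cm per px),
#'   `rotation` (radians), `flip` (logical; y negated before rotating),
#'   `translation` (cm), `rms_residual` (cm).
#' @export
calibrate_from_landmarks <- function(tracked_px, arena, max_rms_cm = 1.0) {
  tracked_px <- as_point_matrix(tracked_px)
  if (nrow(tracked_px) != 4L) stop("exactly 4 landmark points are required")
  if (anyDuplicated(round(tracked_px, 9)))
    stop("degenerate landmarks: duplicated point")
  ctr <- sweep(tracked_px, 2, colMeans(tracked_px))
  if (svd(ctr)$d[2] < 1e-9 * max(1, svd(ctr)$d[1]))
    stop("degenerate landmarks: points are collinear")
  canon <- arena_landmarks(arena)
  best <- NULL
  for (rev_dir in c(FALSE, TRUE)) {
    idx0 <- if (rev_dir) 4:1 else 1:4
    for (shift in 0:3) {
      idx <- idx0[(seq_len(4) + shift - 1L) %% 4L + 1L]
      fit <- fit_similarity(tracked_px, canon[idx, , drop = FALSE])
      if (is.null(best) || fit$rms_residual < best$rms_residual) best <- fit
    }
  }
  if (best$rms_residual > max_rms_cm)
    stop(sprintf("calibration residual %.3f cm exceeds %.3f cm",
                 best$rms_residual, max_rms_cm))
  best
}

# Umeyama-style closed-form similarity fit src -> dst, reflection allowed.
fit_similarity <- function(src, dst) {
  ms <- colMeans(src); md <- colMeans(dst)
  sc <- sweep(src, 2, ms); dc <- sweep(dst, 2, md)
  M <- crossprod(dc, sc)          # 2x2 cross-covariance (dst' src)
  sv <- svd(M)
  A <- sv$u %*% t(sv$v)           # orthogonal, det +1 or -1
  s <- sum(diag(t(A) %*% M)) / sum(sc^2)
  t_vec <- md - s * as.vector(A %*% ms)
  pred <- t(s * A %*% t(src) + t_vec)
  rms <- sqrt(mean(rowSums((pred - dst)^2)))
  flip <- det(A) < 0
  R <- if (flip) A %*% diag(c(1, -1)) else A
  structure(list(scale = s, rotation = atan2(R[2, 1], R[1, 1]), flip = flip,
                 translation = t_vec, rms_residual = rms),
            class = "calibration")
}

calibration_matrix <- function(cal) {
  R <- matrix(c(cos(cal$rotation), sin(cal$rotation),
                -sin(cal$rotation), cos(cal$rotation)), 2, 2)
  if (cal$flip) R %*% diag(c(1, -1)) else R
}

#' Apply or invert a calibration
#'
#' `apply_calibration` maps pixel coordinates to canonical cm coordinates;
#' `invert_calibration` returns the transform in the opposite direction, so
#' that applying one after the other is the identity.
#'
#' @param points n x 2 matrix (or length-2 point).
#' @param cal a `calibration` object.
#' @return transformed n x 2 matrix (`apply_calibration`) or a
#'   `calibration` (`invert_calibration`).
#' @export
apply_calibration <- function(points, cal) {
  p <- as_point_matrix(points)
  A <- cal$scale * calibration_matrix(cal)
  sweep(p %*% t(A), 2, cal$translation, "+")
}

#' @rdname apply_calibration
#' @export
invert_calibration <- function(cal) {
  A <- cal$scale * calibration_matrix(cal)
  Ainv <- solve(A)
  flip <- det(Ainv) < 0
  s <- 1 / cal$scale
  R <- if (flip) Ainv %*% diag(c(1, -1)) / s else Ainv / s
  structure(list(scale = s, rotation = atan2(R[2, 1], R[1, 1]), flip = flip,
                 translation = as.vector(-Ainv %*% cal$translation),
                 rms_residual = cal$rms_residual),
            class = "calibration")
}
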
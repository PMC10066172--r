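# Independent oracles used across the suite. These deliberately use naive
# algorithms (exhaustive enumeration, dense sampling) so they share no code
# path with the implementations they check.

# DTW by exhaustive enumeration of all monotone warping paths, no
# memoization; feasible for series of length <= 6. Same cost convention as
# the package: horizontal/vertical steps weigh the local cost once,
# diagonal steps (and the initial cell) weigh it twice under symmetric2.
dtw_enum_oracle <- function(a, b, step_pattern = "symmetric2") {
  w_diag <- if (step_pattern == "symmetric2") 2 else 1
  rec <- function(i, j) {
    cost <- abs(a[i] - b[j])
    if (i == 1 && j == 1) return(w_diag * cost)
    best <- Inf
    if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1) + w_diag * cost)
    if (i > 1) best <- min(best, rec(i - 1, j) + cost)
    if (j > 1) best <- min(best, rec(i, j - 1) + cost)
    best
  }
  rec(length(a), length(b))
}

# Exact two-sided Mann-Whitney p by full enumeration of all group
# assignments of the pooled sample (no ties assumed).
mw_perm_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_of <- function(idx) {
    xx <- pooled[idx]; yy <- pooled[-idx]
    sum(outer(xx, yy, ">"))
  }
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, u_of)
  u_obs <- sum(outer(x, y, ">"))
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  list(u = u_obs, p = min(1, p))
}

# Minimum distance to a polygon boundary by dense sampling of every edge.
poly_dist_oracle <- function(verts, p, n_per_edge = 1e4) {
  j <- c(seq_len(nrow(verts))[-1], 1L)
  d <- Inf
  for (e in seq_len(nrow(verts))) {
    s <- seq(0, 1, length.out = n_per_edge)
    bx <- verts[e, 1] + s * (verts[j[e], 1] - verts[e, 1])
    by <- verts[e, 2] + s * (verts[j[e], 2] - verts[e, 2])
    d <- min(d, sqrt((bx - p[1])^2 + (by - p[2])^2))
  }
  d
}

# Uniform random points inside an arena by rejection from the bounding box.
runif_in_arena <- function(arena, n) {
  bb <- if (arena$shape_kind == "circle") {
    r <- arena$boundary$radius
    rbind(c(-r, r), c(-r, r))
  } else {
    rbind(range(arena$boundary[, 1]), range(arena$boundary[, 2]))
  }
  out <- matrix(NA_real_, 0, 2)
  while (nrow(out) < n) {
    cand <- cbind(stats::runif(2 * n, bb[1, 1], bb[1, 2]),
                  stats::runif(2 * n, bb[2, 1], bb[2, 2]))
    out <- rbind(out, cand[arena_contains(arena, cand), , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

# A recording built directly from coordinate vectors, for rule tests.
make_rec <- function(x, y, fps = 30, arena = build_arena("circle"),
                     animal_id = "t1", trial_index = 1L, trial_s = 300) {
  tr <- trajectory((seq_along(x) - 1) / fps, x, y, fps = fps)
  trial_recording(tr, arena, animal_id = animal_id,
                  trial_index = trial_index, trial_s = trial_s)
}
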
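#' Partitioning around medoids on a precomputed distance matrix
#'
#' Classical PAM: greedy BUILD initialization followed by best-improvement
#' SWAP until no swap lowers the total within-cluster distance to medoids.
#' Fully deterministic given the matrix: cost ties are broken by lowest
#' index, so the `seed` is recorded for provenance but never changes the
#' result. DTW distances violate the triangle inequality; nothing here
#' assumes it. Cluster numbering is canonicalized by descending cluster
#' size (ties by medoid index) so reports are stable across runs.
#'
#' @param dist_matrix symmetric distance matrix with zero diagonal.
#' @param k number of clusters (2 <= k <= n).
#' @param seed recorded in the result for provenance.
#' @return object of class `clustering_result`: `labels` (1..k per series),
#'   `medoid_indices`, `k`, `total_cost`, `distance_matrix`, `validity`
#'   (from [cluster_validity()], `NULL` when k = n makes it degenerate),
#'   `seed`.
#' @export
pam_cluster <- function(dist_matrix, k = 4, seed = NULL) {
  D <- unname(as.matrix(dist_matrix))
  n <- nrow(D)
  if (k > n) stop(sprintf("k = %d exceeds the %d series available", k, n))
  if (k < 1) stop("k must be at least 1")
  if (max(abs(D - t(D))) > 1e-8 || any(abs(diag(D)) > 1e-12))
    stop("distance matrix must be symmetric with zero diagonal")

  # BUILD: first medoid minimizes total distance; each later medoid
  # maximizes the decrease in cost (ties -> lowest index via which.min/max).
  medoids <- which.min(colSums(D))
  nearest <- D[, medoids]
  while (length(medoids) < k) {
    gain <- vapply(seq_len(n), function(j) {
      if (j %in% medoids) return(-Inf)
      sum(pmax(0, nearest - D[, j]))
    }, 0.0)
    m_new <- which.max(gain)
    medoids <- c(medoids, m_new)
    nearest <- pmin(nearest, D[, m_new])
  }

  cost_of <- function(meds) sum(apply(D[, meds, drop = FALSE], 1, min))
  cost <- cost_of(medoids)

  # SWAP: best-improvement steps; strict improvement required to move.
  repeat {
    best_delta <- -1e-12
    best_swap <- NULL
    for (mi in seq_along(medoids)) {
      others <- medoids[-mi]
      partial <- if (length(others))
        apply(D[, others, drop = FALSE], 1, min) else rep(Inf, n)
      for (h in setdiff(seq_len(n), medoids)) {
        new_cost <- sum(pmin(partial, D[, h]))
        delta <- new_cost - cost
        if (delta < best_delta) {
          best_delta <- delta
          best_swap <- c(mi, h)
        }
      }
    }
    if (is.null(best_swap)) break
    medoids[best_swap[1]] <- best_swap[2]
    cost <- cost_of(medoids)
  }

  labels_raw <- apply(D[, medoids, drop = FALSE], 1, which.min)
  # canonical numbering: descending cluster size, ties by medoid index
  sizes <- tabulate(labels_raw, length(medoids))
  ord <- order(-sizes, medoids)
  relabel <- integer(length(medoids))
  relabel[ord] <- seq_along(medoids)
  labels <- relabel[labels_raw]
  medoids <- medoids[ord]
  validity <- if (k >= 2 && k < n) cluster_validity(D, labels) else NULL
  structure(list(labels = labels, medoid_indices = medoids, k = k,
                 total_cost = cost, distance_matrix = D,
                 validity = validity, seed = seed),
            class = "clustering_result")
}

#' Cluster validity indices from a distance matrix
#'
#' Distance-matrix silhouette (mean and per-point), with the 0/0 -> 0
#' convention for coincident points and silhouette 0 for singletons, plus
#' the ratio of mean within-cluster to mean between-cluster distance.
#'
#' @param dist_matrix symmetric distance matrix.
#' @param labels integer cluster labels (at least 2 distinct).
#' @return list with `silhouette_mean`, `silhouette` (per point) and
#'   `within_between_ratio`.
#' @export
cluster_validity <- function(dist_matrix, labels) {
  D <- as.matrix(dist_matrix)
  n <- nrow(D)
  labs <- unique(labels)
  if (length(labs) < 2) stop("validity indices need at least 2 clusters")
  sil <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) { sil[i] <- 0; next }
    a <- mean(D[i, setdiff(own, i)])
    b <- min(vapply(setdiff(labs, labels[i]),
                    function(l) mean(D[i, labels == l]), 0.0))
    denom <- max(a, b)
    sil[i] <- if (denom < 1e-300) 0 else (b - a) / denom
  }
  within <- D[outer(labels, labels, "==") & upper.tri(D)]
  between <- D[outer(labels, labels, "!=") & upper.tri(D)]
  wb <- if (!length(within) || !length(between) || mean(between) < 1e-300)
    NA_real_ else mean(within) / mean(between)
  list(silhouette_mean = mean(sil), silhouette = sil,
       within_between_ratio = wb)
}

#' Silhouette scan over a range of k
#'
#' Runs [pam_cluster()] for each k and reports the mean silhouette, to
#' support the choice of cluster count.
#'
#' @param dist_matrix symmetric distance matrix.
#' @param k_range candidate cluster counts (default 2..8).
#' @param seed recorded in each result.
#' @return data.frame with columns `k`, `silhouette_mean`, `total_cost`.
#' @export
scan_k <- function(dist_matrix, k_range = 2:8, seed = NULL) {
  rows <- lapply(k_range, function(k) {
    res <- pam_cluster(dist_matrix, k = k, seed = seed)
    val <- if (is.null(res$validity)) NA_real_ else
      res$validity$silhouette_mean
    data.frame(k = k, silhouette_mean = val, total_cost = res$total_cost)
  })
  do.call(rbind, rows)
}

#' Cluster-by-group contingency
#'
#' Counts of cluster labels per group (e.g. arena shape), plus each group's
#' modal cluster.
#'
#' @param result a `clustering_result` or a bare label vector.
#' @param grouping group id per series, aligned with the labels.
#' @return list with `counts` (cluster x group table) and `modal_cluster`
#'   (named vector, one entry per group).
#' @export
cluster_counts <- function(result, grouping) {
  labels <- if (inherits(result, "clustering_result")) result$labels else
    result
  if (!length(labels))
    return(list(counts = table(cluster = integer(0), group = character(0)),
                modal_cluster = integer(0)))
  if (length(labels) != length(grouping))
    stop("labels and grouping must be aligned")
  counts <- table(cluster = labels, group = grouping)
  modal <- apply(counts, 2, function(col)
    as.integer(rownames(counts)[which.max(col)]))
  list(counts = counts, modal_cluster = modal)
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two labelings; 1 for identical
#' partitions, about 0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return the ARI.
#' @export
adjusted_rand <- function(a, b) {
  mclust::adjustedRandIndex(a, b)
}
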
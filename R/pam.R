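new_partition <- function(labels, medoids, objective) {
  structure(list(labels = as.integer(labels),
                 medoids = as.integer(medoids),
                 objective = as.numeric(objective)),
            class = "vf_partition")
}

#' @export
print.vf_partition <- function(x, ...) {
  cat("vf_partition: ", length(x$medoids), " clusters over ",
      length(x$labels), " items, objective ", signif(x$objective, 6),
      "\n", sep = "")
  invisible(x)
}

# assign items to nearest medoid; ties go to the medoid with lower item index
assign_to_medoids <- function(d, medoids) {
  sub <- d[, medoids, drop = FALSE]
  ord <- order(medoids)            # tie-break by medoid item index
  labels <- integer(nrow(d))
  best <- rep(Inf, nrow(d))
  for (j in ord) {
    better <- sub[, j] < best - 1e-12
    labels[better] <- j
    best[better] <- sub[better, j]
  }
  labels[medoids] <- seq_along(medoids)  # a medoid anchors its own cluster
  labels
}

partition_objective <- function(d, medoids) {
  sum(apply(d[, medoids, drop = FALSE], 1L, min))
}

#' k-medoids clustering (PAM) on a distance matrix
#'
#' Classic partitioning around medoids.  For n <= 10 items the medoid set is
#' found by exhaustive search, so the returned objective is the global
#' minimum; for larger problems the standard BUILD initialisation followed
#' by SWAP steepest-descent is used.  All ties (equal distances, equal
#' objectives) break toward the lower item index, so the result is fully
#' deterministic.
#'
#' @param D A [distance_matrix()] result (or plain symmetric matrix).
#' @param k Number of clusters, `1 <= k <= n`.
#' @return Object of class `vf_partition`: integer `labels` (cluster ids
#'   `1..k`, numbered by ascending medoid index), `medoids` (item indices)
#'   and `objective` (total distance of items to their medoid).
#' @export
pam_fit <- function(D, k) {
  D <- as_vf_dist(D)
  n <- D$n
  k <- as.integer(k)
  if (k < 1L || k > n) stop("k must be in 1..", n, " (got ", k, ")")
  d <- D$d
  if (n <= 10L) {
    sets <- utils::combn(n, k)
    objs <- apply(sets, 2L, function(m) partition_objective(d, m))
    best <- sets[, which.min(objs)]   # which.min -> lexicographically first
  } else {
    best <- pam_build(d, k)
    best <- pam_swap(d, best)
  }
  best <- sort(best)
  labels <- assign_to_medoids(d, best)
  new_partition(labels, best, sum(d[cbind(seq_len(n), best[labels])]))
}

pam_build <- function(d, k) {
  n <- nrow(d)
  medoids <- which.min(rowSums(d))
  nearest <- d[, medoids]
  while (length(medoids) < k) {
    gain <- vapply(seq_len(n), function(h) {
      if (h %in% medoids) return(-Inf)
      sum(pmax(nearest - d[, h], 0))
    }, numeric(1))
    h <- which.max(gain)
    medoids <- c(medoids, h)
    nearest <- pmin(nearest, d[, h])
  }
  medoids
}

pam_swap <- function(d, medoids) {
  n <- nrow(d)
  obj <- partition_objective(d, medoids)
  repeat {
    best_obj <- obj
    best_set <- NULL
    for (mi in seq_along(medoids)) {
      for (h in setdiff(seq_len(n), medoids)) {
        cand <- medoids
        cand[mi] <- h
        o <- partition_objective(d, cand)
        if (o < best_obj - 1e-12) {
          best_obj <- o
          best_set <- cand
        }
      }
    }
    if (is.null(best_set)) break
    medoids <- best_set
    obj <- best_obj
  }
  medoids
}
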
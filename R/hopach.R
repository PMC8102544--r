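#' Silhouette widths of a partition
#'
#' Standard silhouette `s(i) = (b(i) - a(i)) / max(a(i), b(i))` where `a` is
#' the mean distance to the item's own cluster (excluding itself) and `b`
#' the smallest mean distance to another cluster.  Items in singleton
#' clusters, and items with `a = b = 0` (exact duplicates everywhere), get
#' `s = 0` by convention.
#'
#' @param D A [distance_matrix()] result (or symmetric matrix).
#' @param labels Integer cluster labels covering >= 2 clusters.
#' @return Numeric vector of silhouette widths in \[-1, 1\].
#' @export
silhouette_widths <- function(D, labels) {
  D <- as_vf_dist(D)
  labels <- as.integer(labels)
  stopifnot(length(labels) == D$n)
  cl <- sort(unique(labels))
  if (length(cl) < 2L) stop("silhouette requires at least 2 clusters")
  d <- D$d
  sizes <- table(factor(labels, levels = cl))
  # mean distance of every item to every cluster
  memb <- outer(labels, cl, "==") + 0
  sums <- d %*% memb
  means_other <- sweep(sums, 2L, as.numeric(sizes), "/")
  s <- numeric(D$n)
  for (i in seq_len(D$n)) {
    ci <- match(labels[i], cl)
    m <- sizes[ci]
    if (m == 1L) { s[i] <- 0; next }
    a <- sums[i, ci] / (m - 1L)
    b <- min(means_other[i, -ci])
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  s
}

#' Split silhouettes of one cluster
#'
#' Measures how cleanly a cluster splits: the cluster's items are
#' re-partitioned by [pam_fit()] over child counts `c` in
#' `2..min(cmax, m - 1)`, the `c` maximising the average silhouette within
#' the cluster is chosen (ties to the smaller `c`), and the items'
#' silhouettes under that best split are returned.  Clusters of size <= 2
#' cannot be split informatively and return zeros.
#'
#' @param D Distance matrix over all items.
#' @param items Integer indices of the cluster's members.
#' @param cmax Maximum child count considered (default 9).
#' @return Numeric vector, one split-silhouette per member of `items`.
#' @export
split_silhouette <- function(D, items, cmax = 9L) {
  D <- as_vf_dist(D)
  items <- as.integer(items)
  if (!length(items)) stop("empty cluster")
  m <- length(items)
  if (m <= 2L) return(numeric(m))
  sub <- as_vf_dist(D$d[items, items, drop = FALSE], D$metric)
  best_sil <- NULL
  best_avg <- -Inf
  for (cc in 2:min(cmax, m - 1L)) {
    p <- pam_fit(sub, cc)
    s <- silhouette_widths(sub, p$labels)
    if (mean(s) > best_avg + 1e-12) {
      best_avg <- mean(s)
      best_sil <- s
    }
  }
  best_sil
}

#' Mean median split silhouette (MSS) of a partition
#'
#' For each cluster the median of its split silhouettes is taken; MSS is the
#' mean of these medians over clusters.  Lower MSS indicates more
#' internally homogeneous clusters; it is the model-selection criterion for
#' the number of clusters in [hopach()].
#'
#' @param D Distance matrix.
#' @param partition A `vf_partition` (or integer label vector).
#' @param cmax Passed to [split_silhouette()].
#' @return Nonnegative scalar (duplicate-only clusters yield 0).
#' @export
mss <- function(D, partition, cmax = 9L) {
  D <- as_vf_dist(D)
  labels <- if (inherits(partition, "vf_partition")) partition$labels else
    as.integer(partition)
  meds <- vapply(sort(unique(labels)), function(cl) {
    stats::median(split_silhouette(D, which(labels == cl), cmax))
  }, numeric(1))
  mean(meds)
}

#' Deterministically order the clusters of a partition
#'
#' Greedy chain on medoid-to-medoid distances: start from the cluster whose
#' medoid has the largest summed distance to all medoids (an extreme of the
#' configuration), then repeatedly append the unplaced cluster whose medoid
#' is nearest to the last placed one.  Ties break toward the lower cluster
#' index.  Cluster ids are renumbered `1..K` along the chain.
#'
#' @param D Distance matrix.
#' @param partition A `vf_partition`.
#' @return A `vf_partition` with clusters renumbered in chain order.
#' @export
order_clusters <- function(D, partition) {
  D <- as_vf_dist(D)
  stopifnot(inherits(partition, "vf_partition"))
  k <- length(partition$medoids)
  if (k == 1L) return(partition)
  dm <- D$d[partition$medoids, partition$medoids, drop = FALSE]
  placed <- which.max(rowSums(dm))
  while (length(placed) < k) {
    rest <- setdiff(seq_len(k), placed)
    nxt <- rest[which.min(dm[placed[length(placed)], rest])]
    placed <- c(placed, nxt)
  }
  relabel <- match(seq_len(k), placed)
  new_partition(relabel[partition$labels], partition$medoids[placed],
                partition$objective)
}

# medoid of an item set: member minimising summed within-set distance,
# ties to the lower item index
set_medoid <- function(d, items) {
  items[which.min(rowSums(d[items, items, drop = FALSE]))]
}

# choose k in 2..kmax minimising MSS of the PAM partition (ties -> smaller k)
best_pam_partition <- function(D, kmax, cmax) {
  ks <- 2:min(kmax, D$n)
  parts <- lapply(ks, function(k) pam_fit(D, k))
  msses <- vapply(parts, function(p) mss(D, p, cmax), numeric(1))
  best <- which(msses <= min(msses) + 1e-12)[1L]
  list(partition = parts[[best]], k = ks[best], mss = msses[best],
       mss_by_k = stats::setNames(msses, ks))
}

# greedy collapsing: repeatedly apply the order-adjacent merge that most
# lowers level MSS, until no merge improves (at most n passes)
collapse_level <- function(D, partition, cmax) {
  d <- D$d
  for (pass in seq_len(D$n)) {
    k <- length(partition$medoids)
    if (k < 2L) break
    cur <- mss(D, partition, cmax)
    best_mss <- cur
    best_part <- NULL
    for (j in seq_len(k - 1L)) {
      lab <- partition$labels
      lab[lab == j + 1L] <- j
      lab[lab > j + 1L] <- lab[lab > j + 1L] - 1L
      cand_mss <- mss(D, lab, cmax)
      if (cand_mss < best_mss - 1e-12) {
        meds <- partition$medoids
        meds[j] <- set_medoid(d, which(lab == j))
        meds <- meds[-(j + 1L)]
        obj <- sum(vapply(seq_along(lab), function(i) d[i, meds[lab[i]]],
                          numeric(1)))
        best_mss <- cand_mss
        best_part <- new_partition(lab, meds, obj)
      }
    }
    if (is.null(best_part)) break
    partition <- best_part
  }
  partition
}

#' HOPACH: hierarchical ordered partitioning and collapsing hybrid
#'
#' Builds a hierarchical tree of PAM partitions.  At the root the number of
#' clusters `k` in `2..kmax` minimising the mean median split silhouette
#' (MSS) is chosen; each cluster of size >= 3 is then recursively
#' partitioned the same way, clusters are deterministically ordered at every
#' level, and (optionally) order-adjacent clusters are greedily collapsed
#' whenever merging lowers the level MSS.  Recursion stops when every
#' cluster has <= 2 items or when the next level raises MSS.  The main
#' partition is the level with minimum MSS (ties to the shallower level).
#' The algorithm is fully deterministic; `seed` is recorded in the result
#' for provenance but unused.
#'
#' @param D A [distance_matrix()] result.
#' @param kmax Maximum cluster count per split (default 9).
#' @param cmax Maximum child count inside the MSS criterion (default 9).
#' @param collapse Enable the collapsing step (default TRUE).
#' @param seed Recorded in the result's parameters; the algorithm draws no
#'   random numbers.
#' @return Object of class `hopach_result`: `levels` (list of
#'   `vf_partition`), `mss_trace`, `main_partition`, `main_level`,
#'   `parameters`.
#' @export
hopach <- function(D, kmax = 9L, cmax = 9L, collapse = TRUE, seed = NULL) {
  D <- as_vf_dist(D)
  if (D$n < 3L) stop("hopach requires at least 3 items")
  root <- best_pam_partition(D, kmax, cmax)$partition
  root <- order_clusters(D, root)
  if (collapse) root <- collapse_level(D, root, cmax)
  levels <- list(root)
  mss_trace <- mss(D, root, cmax)
  repeat {
    cur <- levels[[length(levels)]]
    sizes <- tabulate(cur$labels)
    if (all(sizes <= 2L)) break
    lab <- integer(length(cur$labels))
    meds <- integer(0)
    nxt_k <- 0L
    for (cl in seq_along(cur$medoids)) {
      items <- which(cur$labels == cl)
      if (length(items) >= 3L) {
        subD <- as_vf_dist(D$d[items, items, drop = FALSE], D$metric)
        sub <- best_pam_partition(subD, kmax, cmax)$partition
        sub <- order_clusters(subD, sub)
        lab[items] <- nxt_k + sub$labels
        meds <- c(meds, items[sub$medoids])
        nxt_k <- nxt_k + length(sub$medoids)
      } else {
        lab[items] <- nxt_k + 1L
        meds <- c(meds, set_medoid(D$d, items))
        nxt_k <- nxt_k + 1L
      }
    }
    obj <- sum(vapply(seq_along(lab), function(i) D$d[i, meds[lab[i]]],
                      numeric(1)))
    nxt <- new_partition(lab, meds, obj)
    if (collapse) nxt <- collapse_level(D, nxt, cmax)
    if (identical(nxt$labels, cur$labels)) break   # collapsing undid the split
    m <- mss(D, nxt, cmax)
    if (m > mss_trace[length(mss_trace)] + 1e-12) break
    levels <- c(levels, list(nxt))
    mss_trace <- c(mss_trace, m)
  }
  main_level <- which.min(mss_trace)
  structure(
    list(levels = levels,
         mss_trace = mss_trace,
         main_partition = levels[[main_level]],
         main_level = main_level,
         parameters = list(kmax = kmax, cmax = cmax, collapse = collapse,
                           seed = seed, metric = D$metric, n = D$n)),
    class = "hopach_result"
  )
}

#' @export
print.hopach_result <- function(x, ...) {
  cat("hopach_result: ", length(x$levels), " level(s); main level ",
      x$main_level, " with ", length(x$main_partition$medoids),
      " clusters (MSS ", signif(x$mss_trace[x$main_level], 4), ")\n", sep = "")
  invisible(x)
}

#' Serialize a HOPACH result to JSON
#'
#' @param result A `hopach_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hopach_json <- function(result, path) {
  stopifnot(inherits(result, "hopach_result"))
  obj <- list(
    parameters = result$parameters,
    mss_trace = result$mss_trace,
    main_level = result$main_level,
    levels = lapply(result$levels, function(p)
      list(labels = p$labels, medoids = p$medoids, objective = p$objective))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
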
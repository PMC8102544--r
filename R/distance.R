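#' Pairwise distance matrix between test points
#'
#' Items are the rows of `data` (test points), each described by its profile
#' across eyes (columns).  Supported metrics: `"cosangle"` (1 minus cosine
#' similarity, the conventional choice for expression-style profile
#' clustering and the default here), `"correlation"` ((1 - Pearson r)/2) and
#' `"euclidean"`.
#'
#' @param data Numeric matrix, items in rows (68 x n_eyes for a training
#'   matrix transposed with `t()` -- note [split_train_test()] returns
#'   points in rows already when passed as `training`).
#' @param metric One of `"cosangle"`, `"euclidean"`, `"correlation"`.
#' @return Object of class `vf_dist`: list with `n`, symmetric matrix `d`
#'   (zero diagonal) and `metric`.
#' @export
distance_matrix <- function(data, metric = c("cosangle", "euclidean",
                                             "correlation")) {
  metric <- match.arg(metric)
  data <- as.matrix(data)
  if (nrow(data) < 2L) stop("need at least 2 items (rows)")
  if (any(!is.finite(data))) stop("data must be finite")
  n <- nrow(data)
  if (metric == "euclidean") {
    d <- as.matrix(stats::dist(data))
  } else if (metric == "cosangle") {
    nrm <- sqrt(rowSums(data^2))
    bad <- which(nrm == 0)
    if (length(bad)) {
      stop("zero-norm row(s) under cosangle metric: ",
           paste(bad, collapse = ", "))
    }
    u <- data / nrm
    d <- 1 - tcrossprod(u)
  } else {
    sds <- apply(data, 1L, stats::sd)
    bad <- which(sds == 0)
    if (length(bad)) {
      stop("constant row(s) under correlation metric: ",
           paste(bad, collapse = ", "))
    }
    d <- (1 - stats::cor(t(data))) / 2
  }
  d <- (d + t(d)) / 2          # enforce exact symmetry
  d[d < 0] <- 0                # clip negative rounding residue
  diag(d) <- 0
  dimnames(d) <- NULL
  structure(list(n = n, d = d, metric = metric), class = "vf_dist")
}

as_vf_dist <- function(x, metric = "euclidean") {
  if (inherits(x, "vf_dist")) return(x)
  d <- as.matrix(x)
  stopifnot(nrow(d) == ncol(d), all(is.finite(d)), all(d >= 0),
            isTRUE(all.equal(d, t(d))), all(diag(d) == 0))
  structure(list(n = nrow(d), d = d, metric = metric), class = "vf_dist")
}

#' @export
print.vf_dist <- function(x, ...) {
  cat("vf_dist: ", x$n, " items, metric = ", x$metric, "\n", sep = "")
  invisible(x)
}
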
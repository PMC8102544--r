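#' Ordinary least-squares line fit
#'
#' Closed-form simple linear regression of `values` on `times`; exact on
#' collinear input.  `values` may be a matrix with one series per column, in
#' which case one fit per column is returned.
#'
#' @param times Numeric vector with at least 2 distinct values.
#' @param values Numeric vector (same length) or matrix with
#'   `length(times)` rows.
#' @return Named vector `c(slope, intercept)` (dB/year, dB), or a 2-row
#'   matrix for matrix input.
#' @examples
#' ols_line(c(0, 2), c(-4, -6))   # slope -1, intercept -4
#' @export
ols_line <- function(times, values) {
  times <- as.numeric(times)
  if (length(times) < 2L) stop("need at least 2 visits to fit a trend")
  if (stats::var(times) == 0) stop("visit times have zero variance")
  mat <- is.matrix(values)
  v <- if (mat) values else matrix(as.numeric(values), ncol = 1L)
  if (nrow(v) != length(times)) stop("times and values length mismatch")
  tc <- times - mean(times)
  slope <- colSums(tc * v) / sum(tc^2)
  intercept <- colMeans(v) - slope * mean(times)
  if (mat) rbind(slope = slope, intercept = intercept) else
    c(slope = slope[[1]], intercept = intercept[[1]])
}

new_prediction <- function(eye_id, method, n_used, target_time, td_hat) {
  structure(list(eye_id = eye_id, method = method,
                 n_used = as.integer(n_used),
                 target_time = as.numeric(target_time),
                 td_hat = as.numeric(td_hat)),
            class = "vf_prediction")
}

#' @export
print.vf_prediction <- function(x, ...) {
  cat("vf_prediction: eye ", x$eye_id, ", method ", x$method, ", from ",
      x$n_used, " visits to t = ", round(x$target_time, 2),
      " y; mean predicted TD ", round(mean(x$td_hat), 2), " dB\n", sep = "")
  invisible(x)
}

resolve_target_time <- function(series, n_used, target_time) {
  if (is.null(target_time)) {
    target_time <- if (n_visits(series) >= 10L) series$visits$time[10L] else
      series$visits$time[n_visits(series)]
  }
  if (target_time < series$visits$time[n_used]) {
    stop("target_time (", target_time, ") precedes the last used visit (",
         series$visits$time[n_used], ")")
  }
  target_time
}

#' Sector-wise trend forecast of a visual field
#'
#' For each of the first `n_used` visits the mean TD of every sector is
#' computed and allocated to all points of that sector; each point's
#' allocated series is then extrapolated to `target_time` by an OLS line
#' against visit time.  Points sharing a sector therefore share one
#' predicted value.  Predictions are not truncated or clamped.  Left-eye
#' series are mirrored to the canonical right-eye indexing first.
#'
#' @param series A [vf_series] with at least `n_used` visits.
#' @param map A [sector_map] (right-canonical).
#' @param n_used Number of initial visits used (>= 2).
#' @param target_time Forecast time in years; defaults to the series' 10th
#'   visit time (or last visit when fewer than 10).
#' @return A `vf_prediction` with 68 predicted TD values.
#' @export
sectorwise_predict <- function(series, map, n_used, target_time = NULL) {
  stopifnot(inherits(series, "vf_series"), inherits(map, "sector_map"))
  if (map$laterality != "right") stop("map must be right-canonical")
  n_used <- as.integer(n_used)
  if (n_used < 2L) stop("need n_used >= 2")
  if (n_used > n_visits(series)) {
    stop("n_used (", n_used, ") exceeds available visits (",
         n_visits(series), ") for eye ", series$eye_id)
  }
  series <- mirror_to_right(series)
  target_time <- resolve_target_time(series, n_used, target_time)
  times <- series$visits$time[seq_len(n_used)]
  td <- series$td[seq_len(n_used), , drop = FALSE]
  f <- factor(map$assignment, levels = seq_len(map$K))
  # per-visit sector means, allocated back to the 68 points
  sums <- td %*% outer(map$assignment, seq_len(map$K), "==")
  means <- sweep(sums, 2L, tabulate(f), "/")
  alloc <- means[, map$assignment, drop = FALSE]
  fits <- ols_line(times, alloc)
  new_prediction(series$eye_id, map$name, n_used, target_time,
                 fits["intercept", ] + fits["slope", ] * target_time)
}

#' Pointwise linear regression (PLR) forecast
#'
#' OLS extrapolation of each of the 68 raw TD point series; identical to
#' [sectorwise_predict()] under the map with 68 singleton sectors.
#'
#' @inheritParams sectorwise_predict
#' @return A `vf_prediction`.
#' @export
plr_predict <- function(series, n_used, target_time = NULL) {
  p <- sectorwise_predict(series, sector_map(1:68, name = "PLR"),
                          n_used, target_time)
  p$method <- "PLR"
  p
}

#' Global mean-sensitivity (MS) trend forecast
#'
#' The per-visit mean of all 68 TD values is regressed on time and the
#' extrapolated mean is allocated to every point; identical to
#' [sectorwise_predict()] under the single all-points sector.
#'
#' @inheritParams sectorwise_predict
#' @return A `vf_prediction` (constant across the 68 points).
#' @export
ms_predict <- function(series, n_used, target_time = NULL) {
  p <- sectorwise_predict(series, sector_map(rep(1L, 68), name = "MS"),
                          n_used, target_time)
  p$method <- "MS"
  p
}

#' Mean absolute error between a forecast and an observed field
#'
#' @param prediction A `vf_prediction` or numeric vector of 68 values.
#' @param actual Numeric vector of 68 observed TD values (dB), e.g. a row
#'   of a series' `td` matrix.
#' @return Mean over the 68 points of the absolute prediction error (dB).
#' @export
mae <- function(prediction, actual) {
  p <- if (inherits(prediction, "vf_prediction")) prediction$td_hat else
    as.numeric(prediction)
  a <- as.numeric(actual)
  if (length(p) != length(a)) {
    stop("length mismatch: ", length(p), " predicted vs ", length(a),
         " observed")
  }
  mean(abs(p - a))
}

#' Serialize predictions to CSV
#'
#' One row per point: `eye_id, method, n_used, target_time, point_index,
#' td_hat`.
#'
#' @param predictions A `vf_prediction` or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  if (inherits(predictions, "vf_prediction")) predictions <- list(predictions)
  rows <- do.call(rbind, lapply(predictions, function(p) {
    data.frame(eye_id = p$eye_id, method = p$method, n_used = p$n_used,
               target_time = p$target_time, point_index = 0:67,
               td_hat = p$td_hat)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
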
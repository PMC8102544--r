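#' Construct a longitudinal visual-field series for one eye
#'
#' A `vf_series` holds one eye's longitudinal record: visit metadata
#' (time in years since the first included visit, age, fixation-loss and
#' false-positive rates) and the 68 total-deviation (TD) values of each
#' visit, indexed in the canonical grid order of [vf_grid()].
#'
#' @param eye_id Unique eye identifier (character).
#' @param patient_id Patient identifier; both eyes of a patient share it.
#' @param laterality `"right"` or `"left"`.
#' @param visits Data frame with columns `time` (years, strictly
#'   increasing, first >= 0), `age` (years, may be `NA`), `fl_rate` and
#'   `fp_rate` (fractions in \[0, 1\]).
#' @param td Numeric matrix, one row per visit, 68 columns of TD values (dB).
#' @return Object of class `vf_series`.
#' @export
vf_series <- function(eye_id, patient_id, laterality, visits, td) {
  laterality <- match.arg(laterality, c("right", "left"))
  td <- as.matrix(td)
  if (ncol(td) != 68L) {
    stop("series '", eye_id, "': expected 68 TD columns, got ", ncol(td))
  }
  if (nrow(td) != nrow(visits)) {
    stop("series '", eye_id, "': ", nrow(visits), " visits but ",
         nrow(td), " TD rows")
  }
  if (nrow(visits) < 1L) stop("series '", eye_id, "': no visits")
  need <- c("time", "age", "fl_rate", "fp_rate")
  miss <- setdiff(need, names(visits))
  if (length(miss)) {
    stop("series '", eye_id, "': missing visit columns: ",
         paste(miss, collapse = ", "))
  }
  if (any(diff(visits$time) <= 0)) {
    stop("series '", eye_id, "': visit times must be strictly increasing")
  }
  for (col in need) visits[[col]] <- as.numeric(visits[[col]])
  rates <- c(visits$fl_rate, visits$fp_rate)
  if (any(!is.finite(rates)) || any(rates < 0 | rates > 1)) {
    stop("series '", eye_id, "': reliability rates must lie in [0, 1]")
  }
  dimnames(td) <- NULL
  rownames(visits) <- NULL
  structure(
    list(eye_id = as.character(eye_id),
         patient_id = as.character(patient_id),
         laterality = laterality,
         visits = as.data.frame(visits)[need],
         td = td),
    class = "vf_series"
  )
}

n_visits <- function(series) nrow(series$visits)

#' Construct a cohort of visual-field series
#'
#' @param series List of [vf_series] objects with unique `eye_id`s.
#' @param provenance Optional named list of metadata (seed, config, ...)
#'   carried along and written as header comments by [write_cohort()].
#' @return Object of class `vf_cohort` (a list of series with a
#'   `provenance` attribute).
#' @export
vf_cohort <- function(series, provenance = list()) {
  if (!is.list(series)) stop("'series' must be a list of vf_series")
  ok <- vapply(series, inherits, logical(1), what = "vf_series")
  if (length(series) && !all(ok)) stop("all elements must be vf_series")
  ids <- vapply(series, `[[`, character(1), "eye_id")
  if (anyDuplicated(ids)) {
    stop("duplicate eye_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(series) <- ids
  structure(series, provenance = provenance, class = "vf_cohort")
}

#' @export
print.vf_cohort <- function(x, ...) {
  nv <- vapply(unclass(x), n_visits, integer(1))
  cat("vf_cohort: ", length(x), " eyes, ",
      length(unique(vapply(unclass(x), `[[`, character(1), "patient_id"))),
      " patients, visits per eye ",
      if (length(x)) paste0(min(nv), "-", max(nv)) else "-", "\n", sep = "")
  invisible(x)
}

#' @export
print.vf_series <- function(x, ...) {
  cat("vf_series '", x$eye_id, "' (", x$laterality, " eye, patient ",
      x$patient_id, "): ", n_visits(x), " visits over ",
      round(max(x$visits$time) - min(x$visits$time), 2), " years\n", sep = "")
  invisible(x)
}

#' Re-index a left-eye series to the canonical right-eye point order
#'
#' Visual fields of left eyes are mirror-imaged so that both eyes share one
#' anatomical point indexing.  Because the left-eye grid of [vf_grid()] is
#' defined as the right-eye grid with x negated at the same index, the
#' mirrored TD value at right-eye point `(x, y)` is the left-eye value
#' recorded at `(-x, y)` -- the same index -- so the values are re-indexed by
#' the coordinate-matching permutation (the identity under this convention)
#' and the series is relabelled as right-canonical.  Right-eye series are
#' returned unchanged.
#'
#' @param series A [vf_series].
#' @return A right-canonical `vf_series` with identical TD multisets per visit.
#' @export
mirror_to_right <- function(series) {
  stopifnot(inherits(series, "vf_series"))
  if (series$laterality == "right") return(series)
  gl <- vf_grid("left")
  gr <- vf_grid("right")
  # left point i sits at (x_i, y_i); its mirror image lands on the right-eye
  # point at (-x_i, y_i)
  perm <- match(paste(-gl$x, gl$y), paste(gr$x, gr$y))
  td <- series$td
  td[, perm] <- series$td
  out <- series
  out$td <- td
  out$laterality <- "right"
  out
}

#' Mean-deviation proxy of a visit
#'
#' Unweighted mean of the 68 TD values.  The device's mean deviation uses a
#' proprietary per-point weighting that is not public, so this unweighted
#' mean is used consistently as the MD summary throughout the package.
#'
#' @param td Numeric vector of 68 finite TD values (dB), e.g. one row of a
#'   series' `td` matrix.
#' @return Mean TD in dB.
#' @examples
#' compute_md(rep(-6, 68))
#' @export
compute_md <- function(td) {
  td <- as.numeric(td)
  if (length(td) != 68L) stop("expected 68 TD values, got ", length(td))
  if (any(!is.finite(td))) stop("TD values must be finite")
  mean(td)
}

#' Filter unreliable examinations from a cohort
#'
#' Applies the standard reliability rule: each eye's first examination is
#' removed (a familiarisation effect), then any visit with fixation-loss
#' rate >= `fl_max` or false-positive rate >= `fp_max` (inclusive
#' thresholds) is removed.  Visit times are re-zeroed to the first retained
#' visit and eyes left with fewer than two visits are dropped.  The returned
#' cohort carries a `first_exam_removed` flag in its provenance so a second
#' application is a no-op on the first-exam step, making the filter
#' idempotent.
#'
#' @param cohort A [vf_cohort].
#' @param fl_max Fixation-loss threshold (default 0.20; a visit at exactly
#'   the threshold is unreliable).
#' @param fp_max False-positive threshold (default 0.15, inclusive).
#' @param drop_first_exam Remove each eye's first examination (default TRUE).
#' @return Filtered [vf_cohort] (possibly empty).
#' @export
apply_reliability_filter <- function(cohort, fl_max = 0.20, fp_max = 0.15,
                                     drop_first_exam = TRUE) {
  stopifnot(inherits(cohort, "vf_cohort"))
  stopifnot(fl_max >= 0, fl_max <= 1, fp_max >= 0, fp_max <= 1)
  prov <- attr(cohort, "provenance")
  already <- isTRUE(prov$first_exam_removed)
  out <- list()
  for (s in unclass(cohort)) {
    keep <- rep(TRUE, n_visits(s))
    if (drop_first_exam && !already) keep[1L] <- FALSE
    keep <- keep & !(s$visits$fl_rate >= fl_max | s$visits$fp_rate >= fp_max)
    if (sum(keep) < 2L) next
    v <- s$visits[keep, , drop = FALSE]
    v$time <- v$time - v$time[1L]
    out[[length(out) + 1L]] <- vf_series(
      s$eye_id, s$patient_id, s$laterality, v, s$td[keep, , drop = FALSE]
    )
  }
  prov$first_exam_removed <- isTRUE(drop_first_exam) || already
  vf_cohort(out, provenance = prov)
}

#' Split a cohort into a training matrix and a testing cohort
#'
#' Training: the earliest retained visit of every eye contributes one
#' column, giving a 68 x n_eyes TD matrix used for sector clustering.
#' Testing: eyes with at least `min_visits_test` visits, truncated to their
#' first 10 visits, used for forecast validation.  By default testing eyes
#' also contribute their first visit to the training matrix (set
#' `include_testing_in_training = FALSE` for disjoint sets).
#'
#' @param cohort A filtered [vf_cohort].
#' @param min_visits_test Minimum visit count for the testing set (default 10).
#' @param include_testing_in_training Logical, default TRUE.
#' @return List with `training` (68 x n matrix, columns named by eye_id) and
#'   `testing` (a [vf_cohort] of exactly-10-visit series).
#' @export
split_train_test <- function(cohort, min_visits_test = 10L,
                             include_testing_in_training = TRUE) {
  stopifnot(inherits(cohort, "vf_cohort"))
  nv <- vapply(unclass(cohort), n_visits, integer(1))
  test_ids <- names(cohort)[nv >= min_visits_test]
  train_ids <- if (include_testing_in_training) names(cohort) else
    setdiff(names(cohort), test_ids)
  if (!length(train_ids)) stop("training matrix would be empty")
  training <- vapply(unclass(cohort)[train_ids],
                     function(s) mirror_to_right(s)$td[1L, ], numeric(68))
  testing <- lapply(unclass(cohort)[test_ids], function(s) {
    keep <- seq_len(min(n_visits(s), 10L))
    vf_series(s$eye_id, s$patient_id, s$laterality,
              s$visits[keep, , drop = FALSE], s$td[keep, , drop = FALSE])
  })
  list(training = training,
       testing = vf_cohort(testing, provenance = attr(cohort, "provenance")))
}
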
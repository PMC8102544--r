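td_cols <- sprintf("td_%02d", 0:67)

fmt_num <- function(x) {
  # shortest decimal text that round-trips a double exactly
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    s <- sprintf("%.15g", v)
    if (as.numeric(s) != v) s <- sprintf("%.17g", v)
    s
  }, character(1))
  out
}

#' Write a cohort to the documented CSV format
#'
#' Wide dialect: one row per eye-visit with columns `eye_id`, `patient_id`,
#' `laterality`, `visit_time_years`, `age_years`, `fl_rate`, `fp_rate`,
#' `td_00` ... `td_67` (TD in canonical point order, dB).  Numeric values
#' are written with enough digits to round-trip doubles exactly; provenance
#' metadata is written as `# key: value` header comments.
#'
#' @param cohort A [vf_cohort].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "vf_cohort"))
  prov <- attr(cohort, "provenance")
  con <- file(path, "w")
  on.exit(close(con))
  if (length(prov)) {
    flat <- vapply(prov, function(v) paste(format(v), collapse = " "),
                   character(1))
    writeLines(sprintf("# %s: %s", names(flat), flat), con)
  }
  header <- c("eye_id", "patient_id", "laterality", "visit_time_years",
              "age_years", "fl_rate", "fp_rate", td_cols)
  writeLines(paste(header, collapse = ","), con)
  for (s in unclass(cohort)) {
    for (i in seq_len(n_visits(s))) {
      row <- c(s$eye_id, s$patient_id, s$laterality,
               fmt_num(s$visits$time[i]), fmt_num(s$visits$age[i]),
               fmt_num(s$visits$fl_rate[i]), fmt_num(s$visits$fp_rate[i]),
               fmt_num(s$td[i, ]))
      writeLines(paste(row, collapse = ","), con)
    }
  }
  invisible(path)
}

#' Read a cohort from CSV
#'
#' Accepts the wide dialect written by [write_cohort()] or the long dialect
#' with columns `eye_id`, `visit_time_years`, `point_index`, `td` (one row
#' per eye-visit-point; patient id defaults to the eye id, laterality to
#' right, reliability rates to 0).  Lines starting with `#` are parsed as
#' provenance metadata.  Malformed input (missing columns, TD count other
#' than 68, non-increasing visit times) is rejected with a diagnostic naming
#' the offending eye or column.
#'
#' @param path CSV path.
#' @return A [vf_cohort].
#' @export
read_cohort <- function(path) {
  head_lines <- readLines(path, n = 200L)
  prov_lines <- grep("^#", head_lines, value = TRUE)
  prov <- list()
  for (ln in prov_lines) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) prov[[trimws(m[2])]] <- trimws(m[3])
  }
  if (isTRUE(prov[["first_exam_removed"]] == "TRUE")) {
    prov$first_exam_removed <- TRUE
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        check.names = FALSE)
  long <- all(c("eye_id", "visit_time_years", "point_index", "td") %in% names(df)) &&
    !any(td_cols %in% names(df))
  if (long) {
    df <- stats::reshape(
      df[c("eye_id", "visit_time_years", "point_index", "td")],
      idvar = c("eye_id", "visit_time_years"),
      timevar = "point_index", direction = "wide"
    )
    idx <- as.integer(sub("^td\\.", "", names(df)[-(1:2)]))
    names(df)[-(1:2)] <- sprintf("td_%02d", idx)
    df <- df[c("eye_id", "visit_time_years",
               intersect(td_cols, names(df)))]
    df$patient_id <- df$eye_id
    df$laterality <- "right"
    df$age_years <- NA_real_
    df$fl_rate <- 0
    df$fp_rate <- 0
  }
  need <- c("eye_id", "patient_id", "laterality", "visit_time_years",
            "age_years", "fl_rate", "fp_rate")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("cohort file is missing columns: ", paste(miss, collapse = ", "))
  }
  have_td <- intersect(td_cols, names(df))
  if (length(have_td) != 68L) {
    stop("expected 68 TD columns (td_00..td_67), found ", length(have_td))
  }
  series <- lapply(split(df, factor(df$eye_id, levels = unique(df$eye_id))),
                   function(d) {
    d <- d[order(d$visit_time_years), , drop = FALSE]
    if (anyDuplicated(d$visit_time_years)) {
      stop("eye '", d$eye_id[1], "': duplicate visit time ",
           d$visit_time_years[duplicated(d$visit_time_years)][1])
    }
    vf_series(d$eye_id[1], d$patient_id[1], d$laterality[1],
              data.frame(time = d$visit_time_years, age = d$age_years,
                         fl_rate = d$fl_rate, fp_rate = d$fp_rate),
              as.matrix(d[td_cols]))
  })
  names(series) <- NULL
  vf_cohort(series, provenance = prov)
}
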
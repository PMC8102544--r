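seq_label <- function(n_used) sprintf("1-%d", n_used)

#' Forecast-error table over a testing cohort
#'
#' For every eye (exactly 10 visits each), every sequence length
#' `n` in `sequences`, and every method -- one sector-wise forecast per
#' supplied map, pointwise linear regression (`PLR`) and the global mean
#' trend (`MS`) -- the 10th visit is predicted from the first `n` visits and
#' the mean absolute error against the observed 10th field is recorded.
#'
#' @param cohort A [vf_cohort] of 10-visit series (e.g. the `testing` part
#'   of [split_train_test()]).
#' @param maps Named list of [sector_map]s (default the built-in S1 and S2).
#' @param sequences Integer vector of sequence lengths (default 3:9).
#' @return Data frame of class `mae_table` with columns `eye_id`,
#'   `patient_id`, `method`, `sequence` (label `"1-n"`), `n_used`, `mae`.
#' @export
evaluate_cohort <- function(cohort,
                            maps = list(S1 = builtin_sector_map("S1"),
                                        S2 = builtin_sector_map("S2")),
                            sequences = 3:9) {
  stopifnot(inherits(cohort, "vf_cohort"), length(cohort) > 0)
  if (is.null(names(maps)) || any(names(maps) == "")) {
    names(maps) <- vapply(maps, `[[`, character(1), "name")
  }
  rows <- vector("list", length(cohort))
  for (e in seq_along(cohort)) {
    s <- cohort[[e]]
    if (n_visits(s) != 10L) {
      stop("eye '", s$eye_id, "' has ", n_visits(s),
           " visits; evaluation requires exactly 10")
    }
    s <- mirror_to_right(s)
    actual <- s$td[10L, ]
    t10 <- s$visits$time[10L]
    out <- expand.grid(method = c(names(maps), "PLR", "MS"),
                       n_used = sequences, stringsAsFactors = FALSE)
    out$mae <- mapply(function(meth, n) {
      p <- if (meth == "PLR") plr_predict(s, n, t10)
      else if (meth == "MS") ms_predict(s, n, t10)
      else sectorwise_predict(s, maps[[meth]], n, t10)
      mae(p, actual)
    }, out$method, out$n_used)
    out$eye_id <- s$eye_id
    out$patient_id <- s$patient_id
    rows[[e]] <- out
  }
  tab <- do.call(rbind, rows)
  tab$sequence <- seq_label(tab$n_used)
  tab <- tab[c("eye_id", "patient_id", "method", "sequence", "n_used", "mae")]
  rownames(tab) <- NULL
  class(tab) <- c("mae_table", "data.frame")
  tab
}

#' Mixed-model comparison of two forecasting methods
#'
#' Fits `mae ~ method + (1 | patient_id)` by REML on the rows of one
#' sequence length for two methods, with the subject (patient) as random
#' intercept, and reports the method fixed effect (method_b minus method_a,
#' dB) with its Wald-type t-test p-value (Satterthwaite degrees of
#' freedom).  With one eye per patient the design is balanced-paired and
#' the test reduces to the paired t-test.  Zero random-effect variance
#' (singular fit) is allowed.
#'
#' @param table An `mae_table` from [evaluate_cohort()].
#' @param method_a,method_b Method labels present in the table.
#' @param sequence Sequence label (`"1-3"` ... `"1-9"`) or length.
#' @return Data frame row: `method_a`, `method_b`, `sequence`, `estimate`,
#'   `p` (raw).
#' @export
lmm_compare <- function(table, method_a, method_b, sequence) {
  if (is.numeric(sequence)) sequence <- seq_label(sequence)
  d <- table[table$sequence == sequence &
               table$method %in% c(method_a, method_b), , drop = FALSE]
  if (!nrow(d)) stop("no rows for sequence ", sequence)
  for (m in c(method_a, method_b)) {
    if (!m %in% d$method) stop("method '", m, "' absent for sequence ", sequence)
  }
  if (length(unique(d$patient_id)) < 2L) {
    stop("mixed-model comparison needs at least 2 patients")
  }
  d$method <- factor(d$method, levels = c(method_a, method_b))
  # identical columns give a zero-variance response difference on which the
  # mixed model is degenerate; the paired reduction is exact there
  diffs <- d$mae[d$method == method_b] - d$mae[d$method == method_a]
  if (stats::sd(diffs) == 0) {
    est <- diffs[1L]
    p <- if (est == 0) 1 else 0
  } else {
    fit <- suppressMessages(suppressWarnings(
      lmerTest::lmer(mae ~ method + (1 | patient_id), data = d, REML = TRUE)
    ))
    co <- stats::coef(summary(fit))
    est <- co[2L, "Estimate"]
    p <- co[2L, "Pr(>|t|)"]
    if (!is.finite(p)) stop("mixed model did not yield a finite p-value")
  }
  data.frame(method_a = method_a, method_b = method_b, sequence = sequence,
             estimate = est, p = p, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment via [stats::p.adjust()]; input
#' order is preserved.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, `adjusted >= raw`, capped at 1.
#' @export
bh_adjust <- function(p) {
  p <- as.numeric(p)
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' All pairwise method comparisons with multiplicity correction
#'
#' Runs [lmm_compare()] for every pair of methods and every sequence length
#' in the table (6 pairs x 7 sequences = 42 comparisons for the standard
#' four methods), then applies Benjamini-Hochberg jointly across all raw
#' p-values (set `bh_family = "per_pair"` to adjust within each method pair
#' instead).  Significance is flagged at adjusted p < `alpha`.
#'
#' @param table A complete `mae_table`.
#' @param alpha Significance level (default 0.05).
#' @param bh_family `"joint"` (default) or `"per_pair"`.
#' @return Data frame with `method_a`, `method_b`, `sequence`, `estimate`,
#'   `p`, `p_adj`, `significant`.
#' @export
run_full_comparison <- function(table, alpha = 0.05,
                                bh_family = c("joint", "per_pair")) {
  bh_family <- match.arg(bh_family)
  methods <- unique(table$method)
  seqs <- unique(table$sequence)
  complete <- nrow(table) == length(methods) * length(seqs) *
    length(unique(table$eye_id))
  if (!complete) stop("mae table is incomplete (missing eye/method/sequence cells)")
  pairs <- utils::combn(methods, 2L)
  res <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    do.call(rbind, lapply(seqs, function(sq) {
      lmm_compare(table, pairs[1L, j], pairs[2L, j], sq)
    }))
  }))
  res$p_adj <- if (bh_family == "joint") bh_adjust(res$p) else {
    pa <- numeric(nrow(res))
    key <- paste(res$method_a, res$method_b)
    for (k in unique(key)) pa[key == k] <- bh_adjust(res$p[key == k])
    pa
  }
  res$significant <- res$p_adj < alpha
  rownames(res) <- NULL
  res
}

#' Formatted text report of forecast accuracy
#'
#' Mirrors the conventional presentation: a mean +/- SD block of MAE per
#' method and sequence length, followed by a block of BH-adjusted p-values
#' per method pair (asterisk marks adjusted p < 0.05).
#'
#' @param table An `mae_table`.
#' @param comparisons Optional result of [run_full_comparison()]; computed
#'   from `table` when omitted (requires >= 2 patients).
#' @return Character vector of report lines, invisibly printed with `cat()`
#'   when `print = TRUE`.
#' @param print Print the report to the console (default TRUE).
#' @export
report_comparison <- function(table, comparisons = NULL, print = TRUE) {
  seqs <- unique(table$sequence)
  methods <- unique(table$method)
  lines <- c("Mean absolute error when predicting the 10th VF",
             paste(c(sprintf("%-10s", "MAE (dB)"), sprintf("%9s", seqs)),
                   collapse = ""))
  for (m in methods) {
    cells <- vapply(seqs, function(sq) {
      x <- table$mae[table$method == m & table$sequence == sq]
      sprintf("%.1f\u00b1%.1f", mean(x), stats::sd(x))
    }, character(1))
    lines <- c(lines, paste(c(sprintf("%-10s", m), sprintf("%9s", cells)),
                            collapse = ""))
  }
  if (is.null(comparisons)) comparisons <- run_full_comparison(table)
  lines <- c(lines, "", "Adjusted P values (linear mixed model, BH)",
             paste(c(sprintf("%-12s", "pair"), sprintf("%9s", seqs)),
                   collapse = ""))
  key <- paste(comparisons$method_a, "vs.", comparisons$method_b)
  for (k in unique(key)) {
    sub <- comparisons[key == k, ]
    cells <- vapply(seqs, function(sq) {
      r <- sub[sub$sequence == sq, ]
      sprintf("%s%s", format.pval(r$p_adj, digits = 2, eps = 1e-3),
              if (r$significant) "*" else "")
    }, character(1))
    lines <- c(lines, paste(c(sprintf("%-12s", k), sprintf("%9s", cells)),
                            collapse = ""))
  }
  lines <- c(lines, "*adjusted P < 0.05")
  if (print) cat(lines, sep = "\n")
  invisible(lines)
}

#' Write an MAE table to CSV
#'
#' @param table An `mae_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mae_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
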
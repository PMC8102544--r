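make_table <- function(n_pat = 20, methods = c("A", "B"), offset = 0,
                       seed = 1, eyes_per_patient = 1) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_pat)) {
    for (e in seq_len(eyes_per_patient)) {
      base <- rnorm(1, 5, 1.5)
      for (m in methods) {
        rows[[length(rows) + 1]] <- data.frame(
          eye_id = sprintf("p%02d_e%d", i, e),
          patient_id = sprintf("p%02d", i), method = m, sequence = "1-3",
          n_used = 3L,
          mae = abs(base + (if (m == methods[2]) offset else 0) +
                      rnorm(1, 0, 0.4)))
      }
    }
  }
  tab <- do.call(rbind, rows)
  class(tab) <- c("mae_table", "data.frame")
  tab
}

test_that("cohort evaluation covers every eye, method and sequence", {
  coh <- simulate_cohort(cohort_config("testing", n_eyes = 4, seed = 3))
  tab <- evaluate_cohort(coh)
  expect_equal(nrow(tab), 4 * 4 * 7)
  expect_setequal(unique(tab$method), c("S1", "S2", "PLR", "MS"))
  expect_setequal(unique(tab$sequence), sprintf("1-%d", 3:9))
  expect_true(all(tab$mae >= 0))
  # deterministic: same cohort twice gives the identical table
  expect_identical(evaluate_cohort(coh)$mae, tab$mae)
  # noise-free linear cohort: PLR column is exactly zero
  lin <- vf_cohort(list(linear_series(runif(68, -2, 0), runif(68, -25, 0),
                                      eye = "l1", pat = "q1"),
                        linear_series(runif(68, -2, 0), runif(68, -25, 0),
                                      eye = "l2", pat = "q2")))
  tl <- evaluate_cohort(lin)
  expect_equal(max(tl$mae[tl$method == "PLR"]), 0, tolerance = 1e-8)
  # eye with the wrong number of visits is named in the error
  bad <- vf_cohort(list(random_series("short", nv = 5, seed = 8)))
  expect_error(evaluate_cohort(bad), "short")
})

test_that("the mixed-model comparison recovers known effects", {
  # duplicated method: estimate 0, p ~ 1
  tab0 <- make_table(offset = 0)
  tab0$mae[tab0$method == "B"] <- tab0$mae[tab0$method == "A"]
  r0 <- lmm_compare(tab0, "A", "B", "1-3")
  expect_equal(r0$estimate, 0)
  expect_gt(r0$p, 0.99)
  # exact constant offset: estimate recovered to numerical precision
  tab5 <- make_table(offset = 0)
  tab5$mae[tab5$method == "B"] <- tab5$mae[tab5$method == "A"] + 0.5
  r5 <- lmm_compare(tab5, "A", "B", "1-3")
  expect_equal(r5$estimate, 0.5, tolerance = 1e-8)
  # antisymmetry under swapping the methods
  tab <- make_table(offset = 0.3, seed = 5, eyes_per_patient = 2)
  ra <- lmm_compare(tab, "A", "B", "1-3")
  rb <- lmm_compare(tab, "B", "A", "1-3")
  expect_equal(ra$estimate, -rb$estimate, tolerance = 1e-6)
  expect_equal(ra$p, rb$p, tolerance = 1e-6)
  expect_error(lmm_compare(make_table(n_pat = 1), "A", "B", "1-3"),
               "2 patients")
})

test_that("with one eye per patient the mixed model reduces to the paired t-test", {
  for (seed in 1:20) {
    tab <- make_table(n_pat = 25, offset = 0.15, seed = seed)
    r <- lmm_compare(tab, "A", "B", "1-3")
    a <- tab$mae[tab$method == "A"]
    b <- tab$mae[tab$method == "B"]
    tt <- t.test(b, a, paired = TRUE)
    expect_equal(r$p, tt$p.value, tolerance = 1e-3)
    expect_equal(r$estimate, unname(tt$estimate), tolerance = 1e-6)
  }
})

test_that("Benjamini-Hochberg adjustment matches the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  # hand step-up: m=3, sorted (0.01, 0.04, 0.9) -> (0.03, 0.06, 0.9)
  expect_equal(bh_adjust(c(0.04, 0.9, 0.01)), c(0.06, 0.9, 0.03))
  set.seed(6)
  p <- runif(30)
  expect_true(all(bh_adjust(p) >= p))
  expect_true(all(bh_adjust(p) <= 1))
  # permutation-equivariant
  perm <- sample(30)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("the full comparison yields 42 BH-adjusted results", {
  coh <- simulate_cohort(cohort_config("testing", n_eyes = 10, seed = 9))
  tab <- evaluate_cohort(coh)
  cmp <- run_full_comparison(tab)
  expect_equal(nrow(cmp), 42L)
  expect_true(all(cmp$p_adj >= cmp$p - 1e-12))
  expect_true(all(cmp$p_adj <= 1))
  expect_identical(cmp$significant, cmp$p_adj < 0.05)
  expect_error(run_full_comparison(tab[-1, ]), "incomplete")
  # report renders both blocks
  lines <- report_comparison(tab, cmp, print = FALSE)
  expect_true(any(grepl("S1 vs. PLR", lines)))
  expect_true(any(grepl("Mean absolute error", lines)))
})
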
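test_that("cohort CSV round-trip is lossless and malformed input is rejected", {
  set.seed(42)
  coh <- vf_cohort(list(random_series("e1", "p1"),
                        random_series("e2", "p1", nv = 4, lat = "left")),
                   provenance = list(seed = 42, role = "test"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_identical(names(back), names(coh))
  for (id in names(coh)) {
    expect_identical(back[[id]]$td, coh[[id]]$td)
    expect_identical(back[[id]]$visits, coh[[id]]$visits)
    expect_identical(back[[id]]$laterality, coh[[id]]$laterality)
  }
  expect_equal(attr(back, "provenance")$seed, "42")

  # 67 TD columns -> error naming the count
  txt <- grep("^#", readLines(path), invert = TRUE, value = TRUE)
  txt <- sub(",[^,]*$", "", txt)   # drop the td_67 column everywhere
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(txt, bad)
  expect_error(read_cohort(bad), "68 TD columns")

  # duplicate visit time -> error naming the eye
  df <- utils::read.csv(path, comment.char = "#")
  df$visit_time_years[2] <- df$visit_time_years[1]
  p2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, p2, row.names = FALSE)
  expect_error(read_cohort(p2), "duplicate visit time")
})

test_that("long-dialect files are accepted", {
  s <- random_series("eL", seed = 3, nv = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  long <- do.call(rbind, lapply(seq_len(3), function(v)
    data.frame(eye_id = "eL", visit_time_years = s$visits$time[v],
               point_index = 0:67, td = s$td[v, ])))
  utils::write.csv(long, path, row.names = FALSE)
  back <- read_cohort(path)
  expect_equal(back[["eL"]]$td, s$td, tolerance = 1e-12)
  expect_equal(back[["eL"]]$patient_id, "eL")
})

test_that("reliability filter removes flagged visits inclusively and re-zeroes time", {
  times <- 0:5
  fl <- c(0.05, 0.20, 0.19, 0.02, 0.01, 0.00)   # visit 2 unreliable (FL = 20%)
  fp <- c(0.00, 0.00, 0.14, 0.15, 0.00, 0.10)   # visit 4 unreliable (FP = 15%)
  s <- vf_series("e1", "p1", "right",
                 data.frame(time = times, age = 50 + times,
                            fl_rate = fl, fp_rate = fp),
                 matrix(rep(times, 68), 6, 68))
  coh <- vf_cohort(list(s))
  out <- apply_reliability_filter(coh)
  # first exam dropped, then FL>=0.20 and FP>=0.15 dropped; 0.19/0.14 retained
  expect_equal(n_visits <- nrow(out[["e1"]]$visits), 3L)
  expect_equal(out[["e1"]]$td[, 1], c(2, 4, 5))
  expect_equal(out[["e1"]]$visits$time, c(0, 2, 3))   # re-zeroed
  # idempotent: a second pass changes nothing
  expect_identical(unclass(apply_reliability_filter(out))[], unclass(out)[])

  # eye reduced below 2 visits is dropped
  s2 <- vf_series("e2", "p2", "right", make_visits(c(0, 1)),
                  matrix(0, 2, 68))
  expect_length(apply_reliability_filter(vf_cohort(list(s2))), 0L)
})

test_that("train/test split uses first visits for training and 10-visit eyes for testing", {
  set.seed(7)
  coh <- vf_cohort(list(random_series("e1", "p1", nv = 12),
                        random_series("e2", "p1", nv = 3),
                        random_series("e3", "p2", nv = 10)))
  sp <- split_train_test(coh)
  expect_equal(dim(sp$training), c(68L, 3L))
  expect_equal(sp$training[, "e1"], coh[["e1"]]$td[1, ])
  expect_setequal(names(sp$testing), c("e1", "e3"))
  expect_true(all(vapply(unclass(sp$testing), function(s) nrow(s$visits),
                         integer(1)) == 10L))
  sp2 <- split_train_test(coh, include_testing_in_training = FALSE)
  expect_equal(colnames(sp2$training), "e2")
})

test_that("the MD proxy is the unweighted TD mean", {
  expect_equal(compute_md(rep(0, 68)), 0)
  expect_equal(compute_md(rep(-10, 68)), -10)
  expect_equal(compute_md(c(rep(-4, 34), rep(-8, 34))), -6)
  expect_error(compute_md(c(rep(-4, 67), NA)), "finite")
  expect_error(compute_md(rep(-4, 67)), "68")
})
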
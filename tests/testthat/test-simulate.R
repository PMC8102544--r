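test_that("the TD surface has a preserved centre, a scotoma and a floor", {
  p <- eye_params(island_radius_r0 = 8, constriction_rate_v = 0,
                  depth_L = 30, edge_width_w = 1, global_slope = 0)
  expect_lt(abs(td_surface(0, 0, p)), 0.02)        # healthy centre
  expect_equal(td_surface(8, 0, p), -15)           # half depth at the edge
  expect_equal(td_surface(100, 0, p), -30)         # full scotoma depth
  p2 <- eye_params(2, 0, 40, 0.5, 0, td_floor = -35)
  expect_equal(td_surface(50, 0, p2), -35)         # floored
  # constriction moves the edge inward over time
  p3 <- eye_params(8, 0.5, 30, 1, 0)
  expect_lt(td_surface(6, 8, p3), td_surface(6, 0, p3))
})

test_that("simulated eyes have the configured shape and are reproducible", {
  cfg <- cohort_config("testing", n_eyes = 6, seed = 21)
  coh1 <- simulate_cohort(cfg)
  coh2 <- simulate_cohort(cfg)
  expect_length(coh1, 6L)
  for (id in names(coh1)) {
    expect_identical(coh1[[id]]$td, coh2[[id]]$td)
    expect_identical(coh1[[id]]$visits, coh2[[id]]$visits)
    expect_equal(dim(coh1[[id]]$td), c(10L, 68L))
    expect_true(all(coh1[[id]]$td >= cfg$td_floor))
    expect_true(all(is.finite(coh1[[id]]$td)))
  }
  # two eyes per patient, fellow eyes share the patient id
  pids <- vapply(unclass(coh1), `[[`, character(1), "patient_id")
  expect_equal(max(table(pids)), 2L)
  # different seed changes the data
  coh3 <- simulate_cohort(cohort_config("testing", n_eyes = 6, seed = 22))
  expect_false(identical(coh1[[1]]$td, coh3[[1]]$td))
  # caller's RNG stream is untouched
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(simulate_cohort(cfg)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("a noiseless static eye repeats itself; constriction lowers mean TD", {
  cfg <- cohort_config("testing", n_eyes = 1, seed = 1,
                       noise_global_sd = 0, noise_point_sd = 0)
  p_static <- eye_params(6, 0, 30, 1.5, 0, noise_global_sd = 0,
                         noise_point_sd = 0)
  set.seed(5)
  s <- simulate_eye(cfg, p_static, "e", "p")
  expect_true(all(apply(s$td, 2, function(x) max(x) - min(x)) < 1e-12))
  # Monte-Carlo: with v > 0 mean TD declines in expectation
  set.seed(6)
  declines <- replicate(200, {
    sp <- eye_params(6, 0.3, 30, 1.5, -0.1)
    se <- simulate_eye(cfg, sp, "e", "p")
    mean(se$td[10, ]) - mean(se$td[1, ])
  })
  expect_lt(mean(declines), 0)
})

test_that("pointwise trend fits recover the global slope in the stable interior", {
  cfg <- cohort_config("testing", n_eyes = 1, seed = 1, visits_per_eye = 12)
  p <- eye_params(9.5, 0.05, 30, 0.8, global_slope = -0.4,
                  noise_global_sd = 0, noise_point_sd = 0)
  set.seed(12)
  s <- simulate_eye(cfg, p, "e", "p")
  g <- vf_grid("right")
  interior <- which(g$eccentricity < 3)   # far from the moving edge
  fits <- ols_line(s$visits$time, s$td[, interior])
  expect_equal(unname(fits["slope", ]), rep(-0.4, length(interior)),
               tolerance = 1e-3)
})

test_that("sector-shared noise favours sector-wise over pointwise forecasts", {
  # TD constant within S1 sectors, linear in time, with sector-level shared
  # noise plus point noise: averaging within sectors must help at n = 3
  s1 <- builtin_sector_map("S1")
  set.seed(33)
  gaps <- replicate(30, {
    slopes <- rnorm(s1$K, -0.5, 0.3)[s1$assignment]
    base <- rnorm(s1$K, -12, 5)[s1$assignment]
    times <- (0:9) * 0.9
    td <- outer(times, slopes) + matrix(base, 10, 68, byrow = TRUE) +
      t(replicate(10, rnorm(s1$K, 0, 1)[s1$assignment])) +
      matrix(rnorm(10 * 68, 0, 2), 10, 68)
    s <- vf_series("e", "p", "right", make_visits(times), td)
    truth <- s$td[10, ]
    mae(plr_predict(s, 3, times[10]), truth) -
      mae(sectorwise_predict(s, s1, 3, times[10]), truth)
  })
  expect_gt(mean(gaps), 0)
})
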
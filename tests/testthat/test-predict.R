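test_that("ols_line is exact on hand-solved inputs", {
  f <- ols_line(c(0, 2), c(-4, -6))
  expect_equal(unname(f["slope"]), -1)
  expect_equal(unname(f["intercept"]), -4)
  expect_equal(unname(ols_line(0:4, rep(7, 5))["slope"]), 0)
  # adding a constant shifts the intercept only
  f2 <- ols_line(c(0, 1, 3), c(1, 2, 5) + 10)
  f1 <- ols_line(c(0, 1, 3), c(1, 2, 5))
  expect_equal(f2["slope"], f1["slope"])
  expect_equal(unname(f2["intercept"] - f1["intercept"]), 10)
  expect_error(ols_line(c(1, 1), c(0, 1)), "zero variance")
  expect_error(ols_line(1, 0), "at least 2")
})

test_that("sector-wise forecasting allocates sector means then extrapolates", {
  # two-visit series where one sector's points diverge: sector mean -6, -7
  map <- sector_map(c(rep(1L, 2), rep(2L, 66)), name = "toy")
  td <- matrix(0, 2, 68)
  td[1, 1:2] <- c(-5, -7)
  td[2, 1:2] <- c(-6, -8)
  s <- vf_series("e1", "p1", "right", make_visits(c(0, 1)), td)
  p <- sectorwise_predict(s, map, 2, target_time = 3)
  expect_equal(p$td_hat[1], -9)
  expect_equal(p$td_hat[2], -9)   # same sector, identical prediction
  expect_equal(p$td_hat[3], 0)

  # noise-free sector-constant linear trends are recovered exactly
  s1 <- builtin_sector_map("S1")
  sector_slope <- seq(-1, 1, length.out = s1$K)[s1$assignment]
  lin <- linear_series(sector_slope, rep(-10, 68))
  p10 <- sectorwise_predict(lin, s1, 3)
  expect_equal(mae(p10, lin$td[10, ]), 0, tolerance = 1e-10)

  expect_error(sectorwise_predict(lin, s1, 11), "exceeds")
  expect_error(sectorwise_predict(lin, s1, 3, target_time = 0.5), "precedes")
})

test_that("PLR and MS are sector-wise regression under degenerate maps", {
  for (seed in 1:50) {
    s <- random_series(seed = seed, nv = 10)
    n_used <- sample(2:9, 1)
    tt <- s$visits$time[10]
    plr <- plr_predict(s, n_used, tt)
    via_map <- sectorwise_predict(s, sector_map(1:68), n_used, tt)
    expect_identical(plr$td_hat, via_map$td_hat)
    ms <- ms_predict(s, n_used, tt)
    via_one <- sectorwise_predict(s, sector_map(rep(1L, 68)), n_used, tt)
    expect_identical(ms$td_hat, via_one$td_hat)
    expect_equal(length(unique(ms$td_hat)), 1L)
  }
  # hand-computed cases
  lin <- linear_series(rep(-1, 68), rep(-4, 68), times = c(0, 2))
  expect_equal(plr_predict(lin, 2, 5)$td_hat, rep(-9, 68))
  m <- linear_series(rep(-1, 68), rep(-10, 68), times = c(0, 1))
  expect_equal(ms_predict(m, 2, 9)$td_hat, rep(-19, 68))
})

test_that("pointwise regression nails noise-free linear fields at any length", {
  set.seed(31)
  lin <- linear_series(runif(68, -2, 0), runif(68, -20, 0))
  for (n_used in 2:9) {
    p <- plr_predict(lin, n_used, lin$visits$time[10])
    expect_equal(mae(p, lin$td[10, ]), 0, tolerance = 1e-9)
  }
})

test_that("forecasts are equivariant under spatial mirroring", {
  # mirror the data across the vertical midline and mirror the sector
  # assignment the same way: predictions must mirror along
  s <- random_series(seed = 17)
  perm <- vfsector:::grid_mirror_permutation()
  td2 <- s$td
  td2[, perm] <- s$td
  s2 <- vf_series("e1m", "p1", "right", s$visits, td2)
  s1 <- builtin_sector_map("S1")
  map2 <- sector_map(s1$assignment[perm], name = "S1m")
  a <- sectorwise_predict(s, s1, 4)
  b <- sectorwise_predict(s2, map2, 4)
  expect_equal(b$td_hat[perm], a$td_hat, tolerance = 1e-12)
})

test_that("MAE is the mean absolute pointwise error", {
  expect_equal(mae(c(-1, -3), c(-2, -5)), 1.5)
  expect_equal(mae(rep(0, 68), rep(0, 68)), 0)
  set.seed(4)
  a <- rnorm(68); b <- rnorm(68)
  expect_equal(mae(a, b), mae(b, a))
  expect_gte(mae(a, b), 0)
  expect_error(mae(a, b[-1]), "mismatch")
})
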
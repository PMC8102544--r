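# shared fixture builders (all synthetic, generated in code)

make_visits <- function(times, fl = 0, fp = 0, age = 50) {
  data.frame(time = times, age = age + times, fl_rate = fl, fp_rate = fp)
}

# per-point linear TD: td[v, p] = intercepts[p] + slopes[p] * times[v]
linear_series <- function(slopes, intercepts, times = (0:9) * 0.9,
                          eye = "e1", pat = "p1", lat = "right") {
  td <- outer(times, slopes) + matrix(intercepts, length(times), 68,
                                      byrow = TRUE)
  vf_series(eye, pat, lat, make_visits(times), td)
}

random_series <- function(eye = "e1", pat = "p1", nv = 10, seed = NULL,
                          lat = "right") {
  if (!is.null(seed)) set.seed(seed)
  times <- cumsum(c(0, runif(nv - 1, 0.5, 1.2)))
  td <- matrix(rnorm(nv * 68, -10, 6), nv, 68)
  vf_series(eye, pat, lat, make_visits(times), td)
}

# tiny euclidean distance object from a numeric vector (1-D items)
dist1d <- function(x) distance_matrix(cbind(x, 0), metric = "euclidean")

# independent brute-force k-medoids optimum (enumeration over medoid sets)
brute_pam_objective <- function(d, k) {
  n <- nrow(d)
  min(apply(utils::combn(n, k), 2L,
            function(m) sum(apply(d[, m, drop = FALSE], 1L, min))))
}
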
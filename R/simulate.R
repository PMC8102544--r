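#' Noiseless total-deviation surface of a degenerating field
#'
#' Mechanistic stand-in for concentric field loss in retinitis pigmentosa:
#' a preserved central island of radius `r0` that shrinks at `v` degrees per
#' year, surrounded by a peripheral scotoma of depth `L` dB with a logistic
#' transition of width `w`, on top of a uniform secular decline
#' `global_slope` dB/year; the result is floored at the dynamic-range limit
#' `td_floor`.
#'
#' `TD(r, t) = global_slope * t - L * logistic((r - (r0 - v t)) / w)`
#'
#' @param r Eccentricity in degrees (vectorised).
#' @param t Time in years since baseline.
#' @param params An [eye_params()] list.
#' @return Noiseless TD in dB (same length as `r`).
#' @export
td_surface <- function(r, t, params) {
  stopifnot(all(r >= 0), t >= 0)
  edge <- params$island_radius_r0 - params$constriction_rate_v * t
  td <- params$global_slope * t -
    params$depth_L * stats::plogis((r - edge) / params$edge_width_w)
  pmax(td, params$td_floor)
}

#' Per-eye generative parameters
#'
#' @param island_radius_r0 Preserved central radius at baseline (degrees).
#' @param constriction_rate_v Island shrinkage rate (degrees/year, >= 0).
#' @param depth_L Peripheral loss depth (dB, > 0).
#' @param edge_width_w Logistic transition width (degrees, > 0).
#' @param global_slope Uniform TD decline (dB/year, <= 0).
#' @param noise_global_sd Per-visit fluctuation shared by all 68 points (dB).
#' @param noise_point_sd Independent per-point measurement noise (dB).
#' @param td_floor Dynamic-range floor (dB, <= 0).
#' @return Validated list of class `eye_params`.
#' @export
eye_params <- function(island_radius_r0, constriction_rate_v, depth_L,
                       edge_width_w, global_slope, noise_global_sd = 1,
                       noise_point_sd = 2, td_floor = -35) {
  stopifnot(island_radius_r0 >= 0, constriction_rate_v >= 0, depth_L > 0,
            edge_width_w > 0, global_slope <= 0, noise_global_sd >= 0,
            noise_point_sd >= 0, td_floor <= 0)
  structure(list(island_radius_r0 = island_radius_r0,
                 constriction_rate_v = constriction_rate_v,
                 depth_L = depth_L, edge_width_w = edge_width_w,
                 global_slope = global_slope,
                 noise_global_sd = noise_global_sd,
                 noise_point_sd = noise_point_sd, td_floor = td_floor),
            class = "eye_params")
}

#' Cohort generator configuration
#'
#' Returns the shipped default calibration for either cohort role.  The
#' training defaults emulate the cluster-development cohort (858 eyes, mean
#' age 51.3 +/- 15.7 years, mean baseline MD proxy about -17.9 dB); the
#' testing defaults emulate the validation cohort (196 eyes of ten visits,
#' mean age 47.7 +/- 12.1 years, baseline MD proxy about -16.4 dB, and a
#' mean first-to-tenth-visit span of about 8.1 years from a 0.9-year mean
#' test interval).  Eye-level parameters are truncated-normal draws; the
#' two eyes of a patient share a latent patient effect with inter-eye
#' correlation `inter_eye_correlation`.
#'
#' @param role `"testing"` or `"training"`.
#' @param n_eyes Number of eyes (default 196 testing / 858 training).
#' @param visits_per_eye Visits per eye (default 10).
#' @param seed Integer seed recorded in the cohort provenance.
#' @param ... Named overrides of any default field.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(role = c("testing", "training"), n_eyes = NULL,
                          visits_per_eye = 10L, seed = 1L, ...) {
  role <- match.arg(role)
  cfg <- list(
    role = role,
    n_eyes = if (is.null(n_eyes)) if (role == "testing") 196L else 858L
             else as.integer(n_eyes),
    visits_per_eye = as.integer(visits_per_eye),
    seed = as.integer(seed),
    interval_mean = 0.9,          # years between tests
    interval_sd = 0.15,           # within-eye interval jitter
    interval_between_sd = 0.2,    # eye-to-eye spread of the mean interval
    age_mean = if (role == "testing") 47.7 else 51.3,
    age_sd = if (role == "testing") 12.1 else 15.7,
    age_min = 20,
    inter_eye_correlation = 0.8,
    # eye-level parameter distributions: mean, sd, lower, upper
    island_radius_r0 = if (role == "testing")
      c(mean = 5.2, sd = 3.3, lower = 0, upper = 14) else
      c(mean = 3.5, sd = 4.6, lower = 0, upper = 14),
    constriction_rate_v = c(mean = 0.17, sd = 0.12, lower = 0, upper = 0.6),
    depth_L = if (role == "testing")
      c(mean = 30, sd = 6, lower = 8, upper = 38) else
      c(mean = 32.5, sd = 7, lower = 8, upper = 38),
    edge_width_w = c(mean = 1.5, sd = 0.4, lower = 0.6, upper = 3),
    global_slope = c(mean = -0.15, sd = 0.1, lower = -0.6, upper = 0),
    noise_global_sd = 1,
    noise_point_sd = 2,
    td_floor = -35,
    fl_beta = c(shape1 = 1, shape2 = 4, scale = 0.19),
    fp_beta = c(shape1 = 1, shape2 = 4, scale = 0.14)
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "cohort_config")
}

# truncated-normal draw by inverse CDF (deterministic given the RNG stream)
rtnorm <- function(n, mean, sd, lower, upper) {
  lo <- stats::pnorm((lower - mean) / sd)
  hi <- stats::pnorm((upper - mean) / sd)
  mean + sd * stats::qnorm(stats::runif(n, lo, hi))
}

# correlated eye-level draw: latent = sqrt(rho) z_patient + sqrt(1-rho) z_eye,
# mapped through the truncated-normal inverse CDF
draw_param <- function(spec, z_patient, z_eye, rho) {
  z <- sqrt(rho) * z_patient + sqrt(1 - rho) * z_eye
  lo <- stats::pnorm((spec["lower"] - spec["mean"]) / spec["sd"])
  hi <- stats::pnorm((spec["upper"] - spec["mean"]) / spec["sd"])
  u <- lo + (hi - lo) * stats::pnorm(z)
  unname(spec["mean"] + spec["sd"] * stats::qnorm(u))
}

#' Simulate one eye's longitudinal series
#'
#' Visit times start at 0 and accumulate truncated-normal intervals; each
#' visit's TD is the noiseless [td_surface()] at the point's eccentricity
#' plus a per-visit global fluctuation shared by all 68 points plus
#' independent per-point noise, floored at `td_floor`.  Reliability rates
#' are scaled-beta draws.  Uses the current RNG stream (seed it for
#' reproducibility).
#'
#' @param config A [cohort_config()].
#' @param params An [eye_params()].
#' @param eye_id,patient_id Identifiers.
#' @param laterality `"right"` or `"left"`.
#' @param baseline_age Age at first visit (years).
#' @return A [vf_series].
#' @export
simulate_eye <- function(config, params, eye_id, patient_id,
                         laterality = "right",
                         baseline_age = config$age_mean) {
  nv <- config$visits_per_eye
  m_eye <- max(0.2, stats::rnorm(1, config$interval_mean,
                                 config$interval_between_sd))
  intervals <- pmax(0.05, stats::rnorm(nv - 1L, m_eye, config$interval_sd))
  times <- c(0, cumsum(intervals))
  g <- vf_grid("right")   # TD stored in canonical (mirrored) point order
  r <- g$eccentricity
  td <- matrix(0, nv, 68L)
  for (i in seq_len(nv)) {
    base <- td_surface(r, times[i], params)
    noise <- stats::rnorm(1, 0, params$noise_global_sd) +
      stats::rnorm(68L, 0, params$noise_point_sd)
    td[i, ] <- pmax(base + noise, params$td_floor)
  }
  fl <- config$fl_beta[["scale"]] *
    stats::rbeta(nv, config$fl_beta[["shape1"]], config$fl_beta[["shape2"]])
  fp <- config$fp_beta[["scale"]] *
    stats::rbeta(nv, config$fp_beta[["shape1"]], config$fp_beta[["shape2"]])
  vf_series(eye_id, patient_id, laterality,
            data.frame(time = times, age = baseline_age + times,
                       fl_rate = fl, fp_rate = fp),
            td)
}

#' Simulate a synthetic retinitis-pigmentosa cohort
#'
#' Generates `n_eyes` eyes (two per synthetic patient, parameters
#' correlated between fellow eyes) under the given calibration.
#' Deterministic for a fixed `config$seed`; the caller's RNG state is
#' left untouched.
#'
#' @param config A [cohort_config()].
#' @return A [vf_cohort] with seed/role provenance.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  n <- config$n_eyes
  pars <- c("island_radius_r0", "constriction_rate_v", "depth_L",
            "edge_width_w", "global_slope")
  rho <- config$inter_eye_correlation
  series <- vector("list", n)
  e <- 0L
  pat <- 0L
  while (e < n) {
    pat <- pat + 1L
    pid <- sprintf("P%04d", pat)
    z_pat <- stats::rnorm(length(pars))
    names(z_pat) <- pars
    age <- max(config$age_min, stats::rnorm(1, config$age_mean, config$age_sd))
    for (side in c("right", "left")) {
      if (e >= n) break
      e <- e + 1L
      z_eye <- stats::rnorm(length(pars))
      names(z_eye) <- pars
      vals <- vapply(pars, function(p)
        draw_param(config[[p]], z_pat[p], z_eye[p], rho), numeric(1))
      params <- eye_params(vals["island_radius_r0"],
                           vals["constriction_rate_v"], vals["depth_L"],
                           vals["edge_width_w"], vals["global_slope"],
                           config$noise_global_sd, config$noise_point_sd,
                           config$td_floor)
      series[[e]] <- simulate_eye(config, params,
                                  eye_id = sprintf("%s_%s", pid,
                                                   toupper(substr(side, 1, 1))),
                                  patient_id = pid, laterality = side,
                                  baseline_age = age)
    }
  }
  vf_cohort(series, provenance = list(
    generator = "vfsector::simulate_cohort",
    role = config$role, seed = config$seed, n_eyes = n
  ))
}

#' First-to-last visit span of every eye
#'
#' @param cohort A [vf_cohort].
#' @return Named numeric vector of per-eye spans (years).
#' @export
visit_spans <- function(cohort) {
  vapply(unclass(cohort), function(s) diff(range(s$visits$time)), numeric(1))
}
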
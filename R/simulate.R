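#' Specification for a synthetic running trial
#'
#' The simulator emulates the signal structure steady-state running imposes
#' on the three measurement sites: a periodic stance/swing pattern at a
#' cadence of 120-240 steps/min with alternating sides; a vertical GRF that
#' is zero in swing and a double-hump (rearfoot) or single-hump (forefoot)
#' profile scaled to body weight during stance, constructed so the 10 N
#' up-crossing falls on the true IC sample and the last sample >= 25 N on
#' the true TO sample; a foot resultant impact transient at each right-step
#' IC and a negative-VT dip at each right-step TO (the sensor is on the
#' right foot); a back VT impact peak at every IC and -VT dip at every TO,
#' plus an ML pulse at IC whose sign encodes the step side. White Gaussian
#' noise of `noise_sd` g is added per accelerometer channel. Step times sit
#' on a jittered grid (Gaussian jitter, SD 1% of the step period) so that
#' sliding windows never phase-lock to events.
#'
#' @param cadence steps/min (120-240).
#' @param gct ground contact time, s (>= 0.11 and below the step period);
#'   default 0.68 of the step period, a typical running duty factor.
#' @param duration trial length, s.
#' @param fs accelerometer sampling rate, Hz (>= 50).
#' @param force_fs force-plate sampling rate, Hz (default 1000).
#' @param noise_sd accelerometer noise SD, g.
#' @param impact_amp foot impact peak scale, g (back impact peaks are 0.3 of
#'   this; typical foot impacts are several g).
#' @param to_dip_amp -VT toe-off dip scale, g (back dips are 0.5 of this).
#' @param ml_amp back mediolateral side-signature amplitude, g.
#' @param body_weight N; stance vGRF peaks are ~2.4 body weights.
#' @param foot_strike `"rearfoot"` (double-hump vGRF, sharp impact) or
#'   `"forefoot"` (single-hump, broader impact).
#' @param back_foot_offset_ic,back_foot_offset_to injected timing offsets, s:
#'   back-sensor IC/TO features are shifted by these amounts relative to
#'   truth (for offset-recovery experiments).
#' @param seed integer seed; all randomness flows from it.
#' @return a validated list of class `gait_sim_spec`.
#' @export
gait_sim_spec <- function(cadence = 170, gct = NULL, duration = 60, fs = 200,
                          force_fs = 1000, noise_sd = 0.05, impact_amp = 8,
                          to_dip_amp = 3, ml_amp = 0.3, body_weight = 700,
                          foot_strike = c("rearfoot", "forefoot"),
                          back_foot_offset_ic = 0, back_foot_offset_to = 0,
                          seed = 1L) {
  foot_strike <- match.arg(foot_strike)
  period <- 60 / cadence
  if (is.null(gct)) gct <- 0.68 * period
  stopifnot(cadence >= 120, cadence <= 240, gct >= 0.11, gct < period,
            fs >= 50, force_fs > 0, noise_sd >= 0, duration > 2,
            impact_amp > 0, to_dip_amp > 0, body_weight > 0)
  structure(list(cadence = cadence, gct = gct, duration = duration, fs = fs,
                 force_fs = force_fs, noise_sd = noise_sd,
                 impact_amp = impact_amp, to_dip_amp = to_dip_amp,
                 ml_amp = ml_amp, body_weight = body_weight,
                 foot_strike = foot_strike,
                 back_foot_offset_ic = back_foot_offset_ic,
                 back_foot_offset_to = back_foot_offset_to,
                 seed = as.integer(seed)),
            class = "gait_sim_spec")
}

# evaluate a sum of Gaussian bumps at sample times tt
bumps <- function(tt, centers, amp, width) {
  y <- numeric(length(tt))
  for (c0 in centers) {
    lo <- c0 - 6 * width; hi <- c0 + 6 * width
    i <- which(tt >= lo & tt <= hi)
    if (length(i)) y[i] <- y[i] + amp * exp(-((tt[i] - c0) / width)^2)
  }
  y
}

#' Simulate one co-registered trial triplet with ground truth
#'
#' @param spec a [gait_sim_spec()].
#' @return list with elements `foot` (`triaxial_trial`, raw foot
#'   convention), `back` (`triaxial_trial`, raw unaligned back convention,
#'   tilted 8 degrees in the sagittal plane so gravity alignment is
#'   exercised), `force` (`force_trial`) and `truth` (an [event_table()]
#'   with sides, source `"truth"`).
#' @export
simulate_trial <- function(spec) {
  stopifnot(inherits(spec, "gait_sim_spec"))
  with_seed(spec$seed, simulate_trial_impl(spec))
}

simulate_trial_impl <- function(spec) {
  period <- 60 / spec$cadence
  margin <- 0.5
  grid <- seq(margin, spec$duration - margin - spec$gct, by = period)
  jit <- stats::rnorm(length(grid), 0, 0.01 * period)
  # keep jittered ICs within the contralateral cadence floor
  ic <- grid + pmin(pmax(jit, -0.1 * period), 0.1 * period)
  sides <- rep(c("right", "left"), length.out = length(ic))

  # snap truth to the accelerometer sample grid (common discrete time base),
  # then guarantee the contralateral cadence floor survives the snapping
  ic <- round(ic * spec$fs) / spec$fs
  min_gap_frames <- ceiling(0.25 * spec$fs)
  if (length(ic) > 1L) {
    for (k in 2:length(ic)) {
      ic[k] <- max(ic[k], ic[k - 1L] + min_gap_frames / spec$fs)
    }
  }
  to <- round((ic + spec$gct) * spec$fs) / spec$fs

  force <- simulate_vgrf(spec, ic, to)
  foot <- simulate_foot(spec, ic[sides == "right"], to[sides == "right"])
  back <- simulate_back(spec, ic, to, sides)
  truth <- event_table(kind = rep(c("IC", "TO"), each = length(ic)),
                       t = c(ic, to), side = rep(sides, 2),
                       magnitude = NA_real_, source = "truth",
                       step = rep(seq_along(ic), 2), fs = spec$fs)
  list(foot = foot, back = back, force = force, truth = truth, spec = spec)
}

# stance profile pinned to the threshold crossings: the first and last
# stance samples sit at 50 N (>= both thresholds), swing is exactly zero,
# so the 10 N up-crossing is the IC sample and the last >= 25 N sample the
# TO sample by construction.
simulate_vgrf <- function(spec, ic, to) {
  ffs <- spec$force_fs
  n <- round(spec$duration * ffs)
  v <- numeric(n)
  bw <- spec$body_weight
  for (k in seq_along(ic)) {
    i0 <- round(ic[k] * ffs); i1 <- round(to[k] * ffs)
    u <- seq(0, 1, length.out = i1 - i0 + 1L)
    prof <- if (spec$foot_strike == "rearfoot") {
      1.6 * bw * exp(-((u - 0.25) / 0.12)^2) + 2.2 * bw * exp(-((u - 0.55) / 0.18)^2)
    } else {
      2.4 * bw * exp(-((u - 0.5) / 0.2)^2)
    }
    v[(i0 + 1L):(i1 + 1L)] <- 50 + prof * sin(pi * u)^0.25
  }
  force_trial(v, fs = ffs)
}

simulate_foot <- function(spec, ic_r, to_r) {
  n <- round(spec$duration * spec$fs)
  tt <- (seq_len(n) - 1L) / spec$fs
  w_ic <- if (spec$foot_strike == "rearfoot") 0.020 else 0.030
  vt <- 1 + bumps(tt, ic_r, spec$impact_amp, w_ic) -
    bumps(tt, to_r, spec$to_dip_amp, 0.020)
  ap <- bumps(tt, ic_r, 0.3 * spec$impact_amp, w_ic)
  ml <- numeric(n)
  m <- cbind(ml, ap, vt) + matrix(stats::rnorm(3 * n, 0, spec$noise_sd), n, 3)
  triaxial_trial(m, fs = spec$fs, site = "foot", axis_map = c(ml = 1, ap = 2, vt = 3))
}

simulate_back <- function(spec, ic, to, sides) {
  n <- round(spec$duration * spec$fs)
  tt <- (seq_len(n) - 1L) / spec$fs
  ic_b <- ic + spec$back_foot_offset_ic
  to_b <- to + spec$back_foot_offset_to
  vt <- 1 + bumps(tt, ic_b, 0.3 * spec$impact_amp, 0.025) -
    bumps(tt, to_b, 0.5 * spec$to_dip_amp, 0.025)
  ml <- numeric(n)
  for (k in seq_along(ic_b)) {
    s <- if (sides[k] == "right") 1 else -1
    ml <- ml + s * bumps(tt, ic_b[k], spec$ml_amp, 0.030)
  }
  ap_ant <- 0.1 * sin(2 * pi * tt / (2 * 60 / spec$cadence))
  aligned <- cbind(ml, ap_ant, vt) + matrix(stats::rnorm(3 * n, 0, spec$noise_sd), n, 3)
  # express in the raw sensor frame: tilt 8 deg about ML (sagittal), then
  # the raw back convention (AP + posterior, sensor columns X=ML, Y=VT, Z=AP)
  th <- 8 * pi / 180
  R_tilt <- matrix(c(1, 0, 0,
                     0, cos(th), -sin(th),
                     0, sin(th), cos(th)), 3, 3, byrow = TRUE)
  raw_mlapvt <- aligned %*% R_tilt          # rotate into tilted sensor frame
  raw <- cbind(raw_mlapvt[, 1], raw_mlapvt[, 3], -raw_mlapvt[, 2])  # X=ML, Y=VT, Z=AP_post
  triaxial_trial(raw, fs = spec$fs, site = "back",
                 axis_map = c(ml = 1, ap = 3, vt = 2), aligned = FALSE)
}

#' Simulate a cohort of subjects
#'
#' Per-subject specs are drawn uniformly from the stated ranges (scalars are
#' held fixed), reproducibly under `seed`; each subject's trial seed is
#' derived from the cohort seed.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param ranges named list overriding [gait_sim_spec()] fields; a length-2
#'   numeric entry `c(lo, hi)` is sampled per subject, a scalar is fixed.
#' @param seed cohort seed.
#' @param condition condition label attached to every trial.
#' @return list of [simulate_trial()] results (each also carries
#'   `$condition`).
#' @export
simulate_cohort <- function(n_subjects, ranges = list(cadence = c(150, 192)),
                            seed = 1L, condition = "default") {
  stopifnot(n_subjects >= 1)
  if (any(!nzchar(names(ranges)))) stop("ranges must be named")
  draws <- with_seed(seed, {
    lapply(seq_len(n_subjects), function(i) {
      vals <- lapply(ranges, function(r) {
        if (length(r) == 2 && is.numeric(r)) stats::runif(1, r[1], r[2]) else r
      })
      vals$seed <- stats::runif(1, 1, 2^30)
      vals
    })
  })
  lapply(draws, function(v) {
    out <- do.call(gait_sim_spec, v)
    tr <- simulate_trial(out)
    tr$condition <- condition
    tr
  })
}

# run code under a temporary RNG state; restores (or clears) global state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed %% .Machine$integer.max)
  force(code)
}
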
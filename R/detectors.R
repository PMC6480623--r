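#' Foot detector configuration
#'
#' Candidate admission and cadence settings for the foot (ipsilateral,
#' right-foot) accelerometer detector. The cadence assumptions bound the
#' time between same-foot initial contacts to 0.5-1.0 s (twice the
#' contralateral 0.25-0.5 s bounds, i.e. a cadence of 120-240 steps/min),
#' and toe off occurs no earlier than 0.1 s after initial contact.
#'
#' @param min_ic_separation,max_ic_separation ipsilateral IC spacing bounds, s.
#' @param min_ic_to_gap minimum IC-to-TO gap, s.
#' @param peak_prominence_factor multiplier `k` on the window's MAD-based
#'   spread for adaptive peak admission (dimensionless; no absolute g
#'   threshold is used anywhere).
#' @param quiescence_window seconds before an IC peak within which the
#'   resultant must fall to or below the window median (rejects mid-stance
#'   oscillation peaks).
#' @param search_back fraction of the maximum stance bounding the TO search
#'   region during consolidation.
#' @return a list of class `detector_config`.
#' @export
foot_config <- function(min_ic_separation = 0.5, max_ic_separation = 1.0,
                        min_ic_to_gap = 0.1, peak_prominence_factor = 1.0,
                        quiescence_window = 0.15, search_back = 1.0) {
  stopifnot(min_ic_separation > 0, min_ic_separation < max_ic_separation,
            min_ic_to_gap > 0)
  structure(list(site = "foot", min_ic_separation = min_ic_separation,
                 max_ic_separation = max_ic_separation,
                 min_ic_to_gap = min_ic_to_gap,
                 peak_prominence_factor = peak_prominence_factor,
                 quiescence_window = quiescence_window,
                 search_back = search_back),
            class = "detector_config")
}

#' Back detector configuration
#'
#' Settings for the low-back (bilateral) detector: contralateral IC spacing
#' bounds of 0.25-0.5 s, and the mediolateral-sign rule for left/right step
#' assignment.
#'
#' @inheritParams foot_config
#' @param side_window half-width (s) of the ML interval around an IC used
#'   for side assignment.
#' @param side_sign_right `"+"` (default) if ML acceleration toward +right at
#'   IC marks a right step, `"-"` for the inverted convention.
#' @return a list of class `detector_config`.
#' @export
back_config <- function(min_ic_separation = 0.25, max_ic_separation = 0.5,
                        min_ic_to_gap = 0.1, peak_prominence_factor = 1.0,
                        side_window = 0.05, side_sign_right = c("+", "-")) {
  side_sign_right <- match.arg(side_sign_right)
  stopifnot(min_ic_separation > 0, min_ic_separation < max_ic_separation,
            min_ic_to_gap > 0)
  structure(list(site = "back", min_ic_separation = min_ic_separation,
                 max_ic_separation = max_ic_separation,
                 min_ic_to_gap = min_ic_to_gap,
                 peak_prominence_factor = peak_prominence_factor,
                 side_window = side_window, side_sign_right = side_sign_right),
            class = "detector_config")
}

# shared candidate machinery on precomputed channel vectors; i0 is the
# 0-based frame offset of the window slice within the full trial.
window_candidates <- function(ic_chan, to_chan_vt, fs, i0, k, quiescence = NA) {
  min_prom_ic <- adaptive_prominence(ic_chan, k)
  pk <- find_prominent_peaks(ic_chan, min_prom_ic)
  ic_idx <- pk$idx
  if (length(ic_idx)) {
    # impact peaks stand clear of the window's bulk signal level; filter
    # ringing lobes have prominence but sit close to the median
    med <- stats::median(ic_chan)
    ic_idx <- ic_idx[ic_chan[ic_idx] - med >= min_prom_ic]
  }
  if (length(ic_idx) && is.finite(quiescence)) {
    med <- stats::median(ic_chan)
    nq <- max(1L, round(quiescence * fs))
    ok <- vapply(ic_idx, function(i) {
      lo <- max(1L, i - nq)
      min(ic_chan[lo:i]) <= med
    }, logical(1))
    ic_idx <- ic_idx[ok]
  }
  neg <- -to_chan_vt
  min_prom_to <- adaptive_prominence(neg, k)
  tk <- find_prominent_peaks(neg, min_prom_to)
  list(ic_frame = i0 + ic_idx - 1L, ic_mag = ic_chan[ic_idx],
       to_frame = i0 + tk$idx - 1L, to_mag = neg[tk$idx])
}

#' Per-window foot candidate events
#'
#' IC candidates are prominent local maxima of the resultant acceleration
#' sqrt(ML^2 + AP^2 + VT^2) (impact peaks; the resultant is rotation
#' invariant, so the never-aligned foot sensor needs no orientation
#' correction), admitted when their topographic prominence exceeds
#' `k` x the window's MAD spread and when the resultant falls to the window
#' median or below within `quiescence_window` s before the peak (late-swing
#' quiescence). TO candidates are prominent local minima of the VT axis
#' (peaks of -VT). Magnitudes are the resultant (IC) and -VT (TO) values
#' used later by the consolidation stage; spacing and IC/TO pairing rules
#' are enforced by consolidation, not here.
#'
#' @param window a filtered foot `triaxial_trial` (or segment) of >= 1 s.
#' @param cfg a [foot_config()].
#' @param t0 time of the window's first sample within the full trial, s.
#' @return list with data frames `ic` and `to` (`frame`, `t`, `magnitude`);
#'   empty (with a warning) for windows shorter than 1 s.
#' @export
foot_candidates <- function(window, cfg = foot_config(), t0 = 0) {
  stopifnot(inherits(window, "triaxial_trial"), window$site == "foot")
  fs <- window$fs
  if (n_samples(window) < fs * 1) {
    warning("window shorter than 1 s; no candidates")
    return(empty_pool(fs))
  }
  res <- window_candidates(resultant(window), window$samples[, "VT"], fs,
                           i0 = round(t0 * fs), k = cfg$peak_prominence_factor,
                           quiescence = cfg$quiescence_window)
  pool_from_frames(res, fs)
}

#' Per-window back candidate events
#'
#' IC candidates are prominent local maxima of the VT acceleration (impact
#' peaks visible at the low back for steps of both sides); TO candidates are
#' prominent local minima of VT. The trial must be gravity-aligned first.
#' Side is left unknown at this stage (see [assign_step_side()]).
#'
#' @param window an aligned, filtered back `triaxial_trial` segment >= 1 s.
#' @param cfg a [back_config()].
#' @param t0 time of the window's first sample within the full trial, s.
#' @return as [foot_candidates()].
#' @export
back_candidates <- function(window, cfg = back_config(), t0 = 0) {
  stopifnot(inherits(window, "triaxial_trial"), window$site == "back")
  if (!window$aligned) stop("back trial must be gravity-aligned before detection")
  fs <- window$fs
  if (n_samples(window) < fs * 1) {
    warning("window shorter than 1 s; no candidates")
    return(empty_pool(fs))
  }
  vt <- window$samples[, "VT"]
  res <- window_candidates(vt, vt, fs, i0 = round(t0 * fs),
                           k = cfg$peak_prominence_factor, quiescence = NA)
  pool_from_frames(res, fs)
}

#' Assign a step side from the back mediolateral axis
#'
#' The mean ML acceleration over `[t - side_window, t + side_window]` around
#' an initial contact encodes the stance side: with the default convention a
#' positive (rightward) mean marks a right step. A mean of exactly zero is
#' deterministically assigned left; an interval extending outside the trial
#' yields `"unknown"`.
#'
#' @param trial an aligned back `triaxial_trial`.
#' @param t_ic initial contact time, s.
#' @param cfg a [back_config()].
#' @return `"left"`, `"right"` or `"unknown"`.
#' @export
assign_step_side <- function(trial, t_ic, cfg = back_config()) {
  stopifnot(inherits(trial, "triaxial_trial"), trial$site == "back")
  if (!trial$aligned) stop("back trial must be gravity-aligned before side assignment")
  fs <- trial$fs
  n <- n_samples(trial)
  i0 <- floor((t_ic - cfg$side_window) * fs) + 1L
  i1 <- ceiling((t_ic + cfg$side_window) * fs) + 1L
  if (i0 < 1L || i1 > n) return("unknown")
  m <- mean(trial$samples[i0:i1, "ML"])
  s <- if (cfg$side_sign_right == "+") m else -m
  if (s > 0) "right" else "left"
}

empty_pool <- function(fs) {
  e <- data.frame(frame = integer(), t = numeric(), magnitude = numeric())
  structure(list(ic = e, to = e, fs = fs), class = "candidate_pool")
}

pool_from_frames <- function(res, fs) {
  structure(list(
    ic = data.frame(frame = res$ic_frame, t = res$ic_frame / fs,
                    magnitude = res$ic_mag),
    to = data.frame(frame = res$to_frame, t = res$to_frame / fs,
                    magnitude = res$to_mag),
    fs = fs
  ), class = "candidate_pool")
}
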
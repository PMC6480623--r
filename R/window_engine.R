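#' Sliding-window parameters
#'
#' The engine emulates real-time processing by evaluating overlapping
#' fixed-length windows advanced by a fixed change in window start time.
#' The optimization grid spans sampling rates {50, 100, 200} Hz, window
#' sizes {1, 2, 5} s and shifts {0.005, 0.01, 0.02, 0.1, 0.5, 1} s; the
#' defaults (200 Hz, 2 s, 0.02 s) are the accuracy/throughput compromise
#' used for all downstream analyses. Non-overlapping grids (shift > window)
#' are permitted but risk skipped steps.
#'
#' @param fs sampling rate, Hz.
#' @param window_size window length, s.
#' @param shift change in window start time, s (> 0).
#' @return a list of class `window_params`.
#' @export
window_params <- function(fs = 200, window_size = 2, shift = 0.02) {
  stopifnot(fs > 0, shift > 0, window_size * fs >= 2)
  structure(list(fs = fs, window_size = window_size, shift = shift),
            class = "window_params")
}

#' Collect unique candidate events over sliding windows
#'
#' Evaluates the site's per-window detector on windows
#' `[origin + k*shift, origin + k*shift + window_size)` for k = 0, 1, ...,
#' merging candidates into a pool keyed by (kind, frame index) so that
#' duplicates from overlapping windows are retained once. A final partial
#' window is processed if at least 1 s long. The trial must already be
#' preprocessed (aligned where applicable, low-pass filtered, at the target
#' sampling rate).
#'
#' @param trial a preprocessed trial of the matching class.
#' @param site `"foot"`, `"back"` or `"force"`.
#' @param params a [window_params()].
#' @param cfg detector configuration ([foot_config()] / [back_config()]);
#'   ignored for force.
#' @param origin offset of the window grid, s (for phase-invariance checks).
#' @return a `candidate_pool`: list with data frames `ic`, `to`
#'   (`frame`, `t`, `magnitude`, time-ordered, unique) and `fs`.
#' @export
collect_candidates <- function(trial, site = c("foot", "back", "force"),
                               params = window_params(), cfg = NULL,
                               origin = 0) {
  site <- match.arg(site)
  fs <- trial$fs
  stopifnot(abs(fs - params$fs) < 1e-6)
  if (is.null(cfg)) cfg <- switch(site, foot = foot_config(), back = back_config(), NULL)
  n <- n_samples(trial)
  dur <- n / fs
  wlen <- round(params$window_size * fs)

  # precompute detection channels once; windows only slice them
  if (site == "force") {
    v <- trial$vgrf
  } else if (site == "foot") {
    ic_chan <- resultant(trial)
    to_chan <- trial$samples[, "VT"]
  } else {
    if (!trial$aligned) stop("back trial must be gravity-aligned before detection")
    ic_chan <- trial$samples[, "VT"]
    to_chan <- ic_chan
  }

  ic_frames <- integer(0); ic_mags <- numeric(0)
  to_frames <- integer(0); to_mags <- numeric(0)
  k <- 0L; n_full <- 0L; n_partial <- 0L
  repeat {
    s <- origin + k * params$shift
    i0 <- round(s * fs)
    if (n - i0 < fs * 1) break           # remaining data < 1 s: stop
    i1 <- min(i0 + wlen, n)              # final partial window allowed
    if (i1 - i0 == wlen) n_full <- n_full + 1L else n_partial <- n_partial + 1L
    idx <- (i0 + 1L):i1
    res <- if (site == "force") {
      force_window_candidates(v[idx], fs, i0)
    } else if (site == "foot") {
      window_candidates(ic_chan[idx], to_chan[idx], fs, i0,
                        k = cfg$peak_prominence_factor,
                        quiescence = cfg$quiescence_window)
    } else {
      window_candidates(ic_chan[idx], to_chan[idx], fs, i0,
                        k = cfg$peak_prominence_factor, quiescence = NA)
    }
    ic_frames <- c(ic_frames, res$ic_frame); ic_mags <- c(ic_mags, res$ic_mag)
    to_frames <- c(to_frames, res$to_frame); to_mags <- c(to_mags, res$to_mag)
    k <- k + 1L
  }
  dedupe <- function(fr, mg) {
    if (!length(fr)) return(data.frame(frame = integer(), t = numeric(), magnitude = numeric()))
    o <- order(fr)
    fr <- fr[o]; mg <- mg[o]
    keep <- c(TRUE, diff(fr) > 0L)
    data.frame(frame = fr[keep], t = fr[keep] / fs, magnitude = mg[keep])
  }
  structure(list(ic = dedupe(ic_frames, ic_mags), to = dedupe(to_frames, to_mags),
                 fs = fs, duration = dur, n_windows = n_full, n_partial = n_partial),
            class = "candidate_pool")
}

#' Consolidate a candidate pool into a final event table
#'
#' Walks the time-ordered IC candidates in consecutive triples: when two
#' consecutive potential ICs are closer than the site's minimum separation
#' (0.5 s ipsilateral foot, 0.25 s contralateral back/force), each is tested
#' for cadence viability - its distance to the previously retained IC and to
#' the next potential IC must lie within the [min, max] separation bounds.
#' If exactly one is viable it is retained; otherwise the one with the
#' greater candidate magnitude is retained (ties to the earlier). A
#' candidate closer than the minimum separation to the previously retained
#' IC is dropped. Then, per retained IC: TO candidates at or before the IC,
#' earlier than IC + 0.1 s, or at/after the next IC are inadmissible; among
#' the admissible ones the greatest -VT (or vGRF) magnitude is retained
#' (ties to the earlier). ICs with no admissible TO are kept as IC-only
#' steps. Events within 0.1 s of the trial edges are flagged provisional.
#'
#' Consolidation is idempotent: re-consolidating the pool formed from its
#' own output returns the same table.
#'
#' @param pool a `candidate_pool` from [collect_candidates()].
#' @param cfg a [foot_config()] or [back_config()] (supplies the cadence
#'   bounds), or `NULL` for force defaults (0.25-0.5 s).
#' @param source source label for the resulting events.
#' @param duration trial duration, s (for provisional edge flags); defaults
#'   to the pool's recorded duration.
#' @return an [event_table()].
#' @export
consolidate <- function(pool, cfg = NULL, source = "force", duration = NULL) {
  min_sep <- if (is.null(cfg)) 0.25 else cfg$min_ic_separation
  max_sep <- if (is.null(cfg)) 0.5 else cfg$max_ic_separation
  min_gap <- if (is.null(cfg)) 0.1 else cfg$min_ic_to_gap
  fs <- pool$fs
  if (is.null(duration)) duration <- pool$duration
  tt <- pool$ic$t; mg <- pool$ic$magnitude
  eps <- 1e-9
  # a candidate is cadence-viable when it is not too close to the previously
  # retained IC nor to the next potential IC; exceeding the maximum
  # separation is not disqualifying (a large gap signals a missed detection,
  # not an implausible contact)
  viable <- function(t, prev, nxt) {
    ok_prev <- !is.finite(prev) || (t - prev) >= min_sep - eps
    ok_next <- is.na(nxt) || (nxt - t) >= min_sep - eps
    ok_prev && ok_next
  }
  kept_t <- numeric(0); kept_m <- numeric(0)
  prev <- -Inf
  i <- 1L
  while (i <= length(tt)) {
    if (i < length(tt) && (tt[i + 1L] - tt[i]) < min_sep - eps) {
      nxt <- if (i + 2L <= length(tt)) tt[i + 2L] else NA_real_
      v1 <- viable(tt[i], prev, nxt)
      v2 <- viable(tt[i + 1L], prev, nxt)
      drop <- if (v1 && !v2) i + 1L
      else if (v2 && !v1) i
      else if (mg[i + 1L] > mg[i]) i else i + 1L   # tie -> earlier
      tt <- tt[-drop]; mg <- mg[-drop]
      # re-examine the winner against the new neighbour
    } else if (tt[i] - prev < min_sep - eps) {
      tt <- tt[-i]; mg <- mg[-i]
    } else {
      kept_t <- c(kept_t, tt[i]); kept_m <- c(kept_m, mg[i])
      prev <- tt[i]
      i <- i + 1L
    }
  }
  n_ic <- length(kept_t)
  if (!n_ic) return(event_table(fs = fs, source = source))
  # TO selection per retained IC
  to_t <- rep(NA_real_, n_ic); to_m <- rep(NA_real_, n_ic)
  for (j in seq_len(n_ic)) {
    lo <- kept_t[j] + min_gap
    hi <- if (j < n_ic) kept_t[j + 1L] else kept_t[j] + max_sep
    adm <- pool$to$t >= lo - eps & pool$to$t < hi - eps & pool$to$t > kept_t[j]
    if (any(adm)) {
      cand_t <- pool$to$t[adm]; cand_m <- pool$to$magnitude[adm]
      best <- which(cand_m >= max(cand_m) - eps)[1L]  # tie -> earlier
      to_t[j] <- cand_t[best]; to_m[j] <- cand_m[best]
    }
  }
  has_to <- !is.na(to_t)
  edge <- function(x) x < 0.1 | x > duration - 0.1
  event_table(kind = c(rep("IC", n_ic), rep("TO", sum(has_to))),
              t = c(kept_t, to_t[has_to]),
              magnitude = c(kept_m, to_m[has_to]),
              source = source,
              step = c(seq_len(n_ic), which(has_to)),
              provisional = c(edge(kept_t), edge(to_t[has_to])),
              fs = fs)
}

#' End-to-end gait event detection for one trial
#'
#' Convenience pipeline: resample to the engine's sampling rate, preprocess
#' per site (gravity alignment for an unaligned back trial; 10 Hz
#' fourth-order zero-lag Butterworth low-pass for all sites), collect
#' candidates over sliding windows, consolidate, and - for the back - assign
#' a left/right side to every retained IC.
#'
#' @param trial a raw `triaxial_trial` or `force_trial`.
#' @param params a [window_params()].
#' @param cfg detector configuration; site defaults when `NULL`.
#' @param cutoff,order low-pass settings (10 Hz, order 4).
#' @param origin window-grid offset, s.
#' @return an [event_table()] with source set to the site.
#' @export
detect_trial <- function(trial, params = window_params(), cfg = NULL,
                         cutoff = 10, order = 4, origin = 0) {
  site <- if (inherits(trial, "force_trial")) "force" else trial$site
  if (abs(trial$fs - params$fs) > 1e-6) trial <- resample_trial(trial, params$fs)
  if (site == "back" && !trial$aligned) trial <- align_back_to_gravity(trial)
  if (duration(trial) < 1) {
    warning("trial shorter than 1 s; no events")
    return(event_table(fs = params$fs, source = site))
  }
  trial <- lowpass_trial(trial, cutoff = cutoff, order = order)
  if (is.null(cfg) && site != "force") {
    cfg <- switch(site, foot = foot_config(), back = back_config())
  }
  pool <- collect_candidates(trial, site, params, cfg, origin = origin)
  tab <- consolidate(pool, cfg, source = site)
  if (site == "back" && nrow(tab)) {
    bcfg <- if (is.null(cfg)) back_config() else cfg
    ic_rows <- which(tab$kind == "IC")
    sides <- vapply(tab$t[ic_rows], function(ti) assign_step_side(trial, ti, bcfg),
                    character(1))
    tab$side[ic_rows] <- sides
    tab$side[tab$kind == "TO"] <- sides[match(tab$step[tab$kind == "TO"],
                                              tab$step[ic_rows])]
  }
  tab
}

#' Measure the streaming output rate of the engine
#'
#' Emulates real-time operation: windows are processed in order, and for
#' each data frame a timer runs from the first window in which the frame
#' appears until the window grid has passed it and all candidates up to it
#' have been re-consolidated. The per-frame output rate is 1 / elapsed wall
#' time. Values are hardware-dependent and are reported for information
#' only, never used in pass/fail logic.
#'
#' @inheritParams detect_trial
#' @return list with `mean` (Hz) and `rates` (per-frame Hz).
#' @export
measure_output_rate <- function(trial, params = window_params(), cfg = NULL) {
  site <- if (inherits(trial, "force_trial")) "force" else trial$site
  if (abs(trial$fs - params$fs) > 1e-6) trial <- resample_trial(trial, params$fs)
  if (site == "back" && !trial$aligned) trial <- align_back_to_gravity(trial)
  if (duration(trial) < 1) return(list(mean = NA_real_, rates = numeric(0)))
  trial <- lowpass_trial(trial)
  if (is.null(cfg) && site != "force") {
    cfg <- switch(site, foot = foot_config(), back = back_config())
  }
  fs <- trial$fs
  n <- n_samples(trial)
  wlen <- round(params$window_size * fs)
  first_seen <- rep(NA_real_, n)
  done <- rep(NA_real_, n)
  single <- function(i0, i1) {
    seg <- window_slice(trial, i0, i1)
    res <- switch(site,
      force = {
        p <- force_window_candidates(trial$vgrf[(i0 + 1L):i1], fs, i0)
        pool_from_frames(p, fs)
      },
      foot = foot_candidates(seg, cfg, t0 = i0 / fs),
      back = back_candidates(seg, cfg, t0 = i0 / fs))
    res
  }
  pool_ic <- data.frame(frame = integer(), t = numeric(), magnitude = numeric())
  pool_to <- pool_ic
  k <- 0L
  repeat {
    i0 <- round(k * params$shift * fs)
    if (n - i0 < fs * 1) break
    i1 <- min(i0 + wlen, n)
    now <- proc.time()[["elapsed"]]
    new <- (i0 + 1L):i1
    first_seen[new] <- ifelse(is.na(first_seen[new]), now, first_seen[new])
    res <- suppressWarnings(single(i0, i1))
    pool_ic <- merge_pool(pool_ic, res$ic)
    pool_to <- merge_pool(pool_to, res$to)
    # frames the grid has passed are final: consolidate up to the window start
    passed <- which(is.na(done) & seq_len(n) <= i0)
    if (length(passed)) {
      sub <- structure(list(ic = pool_ic[pool_ic$frame <= i0, , drop = FALSE],
                            to = pool_to[pool_to$frame <= i0, , drop = FALSE],
                            fs = fs, duration = i0 / fs), class = "candidate_pool")
      consolidate(sub, cfg, source = site)
      done[passed] <- proc.time()[["elapsed"]]
    }
    k <- k + 1L
  }
  done[is.na(done)] <- proc.time()[["elapsed"]]
  ok <- !is.na(first_seen)
  dt <- pmax(done[ok] - first_seen[ok], .Machine$double.eps)
  rates <- 1 / dt
  list(mean = mean(rates), rates = rates)
}

merge_pool <- function(a, b) {
  out <- rbind(a, b)
  out <- out[order(out$frame), , drop = FALSE]
  out[c(TRUE, diff(out$frame) > 0L), , drop = FALSE]
}

window_slice <- function(trial, i0, i1) {
  out <- trial
  if (inherits(trial, "force_trial")) out$vgrf <- trial$vgrf[(i0 + 1L):i1]
  else out$samples <- trial$samples[(i0 + 1L):i1, , drop = FALSE]
  out
}
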
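#' Detect gait events from vertical ground reaction force
#'
#' Gold-standard detection: initial contact (IC) is the first sample at or
#' above `ic_threshold` (10 N) following a below-threshold interval, and toe
#' off (TO) is the last sample at or above `to_threshold` (25 N) within that
#' stance. Stances whose TO would fall earlier than `min_ic_to_gap` (0.1 s)
#' after the IC are treated as noise and dropped entirely. Consecutive ICs
#' must be at least `min_ic_separation` apart (0.25 s when both feet strike
#' one plate, i.e. contralateral steps; set 0.5 s for a single-foot plate);
#' a stance starting too soon after the previous retained IC is dropped.
#' Event times are sample times (no sub-sample interpolation), keeping force
#' and accelerometer events on a common discrete time base.
#'
#' @param trial a [force_trial()], low-pass filtered (see [lowpass_trial()]).
#' @param ic_threshold,to_threshold thresholds in N.
#' @param min_ic_to_gap minimum IC-to-TO gap, s.
#' @param min_ic_separation minimum spacing of consecutive ICs, s; set to
#'   `NULL` (or 0) to disable the cadence constraint.
#' @param mark_edges flag events within 0.1 s of the trial edges provisional.
#' @return an [event_table()] with source `"force"`; magnitudes are the vGRF
#'   values at the event samples.
#' @export
detect_force_events <- function(trial, ic_threshold = 10, to_threshold = 25,
                                min_ic_to_gap = 0.1, min_ic_separation = 0.25,
                                mark_edges = TRUE) {
  stopifnot(inherits(trial, "force_trial"))
  stopifnot(ic_threshold > 0, to_threshold > 0)
  if (is.null(min_ic_separation)) min_ic_separation <- 0
  v <- trial$vgrf
  fs <- trial$fs
  if (all(v >= ic_threshold)) {
    warning("no swing phase found: signal never drops below the IC threshold")
    return(event_table(fs = fs, source = "force"))
  }
  st <- stance_bounds(v, ic_threshold, to_threshold)
  if (!nrow(st)) return(event_table(fs = fs, source = "force"))
  keep <- (st$to - st$ic) / fs >= min_ic_to_gap - 1e-12
  st <- st[keep, , drop = FALSE]
  if (min_ic_separation > 0 && nrow(st) > 1L) {
    ok <- rep(TRUE, nrow(st))
    last <- st$ic[1]
    for (i in seq_len(nrow(st))[-1]) {
      if ((st$ic[i] - last) / fs < min_ic_separation - 1e-12) ok[i] <- FALSE
      else last <- st$ic[i]
    }
    st <- st[ok, , drop = FALSE]
  }
  build_force_table(st, v, fs, n_samples(trial), mark_edges)
}

# maximal runs with vgrf >= ic_thr; per run the IC sample and the last
# sample >= to_thr (NA when the run never reaches to_thr). 1-based indices.
stance_bounds <- function(v, ic_thr, to_thr) {
  above <- v >= ic_thr
  d <- diff(c(FALSE, above, FALSE))
  starts <- which(d == 1L)
  ends <- which(d == -1L) - 1L
  if (!length(starts)) return(data.frame(ic = integer(), to = integer()))
  to <- mapply(function(s, e) {
    w <- which(v[s:e] >= to_thr)
    if (length(w)) s + w[length(w)] - 1L else NA_integer_
  }, starts, ends)
  out <- data.frame(ic = starts, to = to, end = ends)
  out[!is.na(out$to), , drop = FALSE]
}

build_force_table <- function(st, v, fs, n, mark_edges) {
  if (!nrow(st)) return(event_table(fs = fs, source = "force"))
  t_ic <- (st$ic - 1L) / fs
  t_to <- (st$to - 1L) / fs
  prov <- if (mark_edges) {
    edge <- function(tt) tt < 0.1 | tt > (n - 1L) / fs - 0.1
    c(edge(t_ic), edge(t_to))
  } else FALSE
  event_table(kind = rep(c("IC", "TO"), each = nrow(st)),
              t = c(t_ic, t_to),
              magnitude = c(v[st$ic], v[st$to]),
              source = "force",
              step = rep(seq_len(nrow(st)), 2),
              provisional = prov, fs = fs)
}

# per-window force candidates for the sliding-window engine: only stances
# strictly interior to the window (below threshold on both sides within the
# window) are emitted; truncated stances are picked up by later windows.
force_window_candidates <- function(v_win, fs, i0, ic_thr = 10, to_thr = 25,
                                    min_gap = 0.1) {
  st <- stance_bounds(v_win, ic_thr, to_thr)
  if (nrow(st)) {
    interior <- st$ic > 1L & st$end < length(v_win)
    st <- st[interior & (st$to - st$ic) / fs >= min_gap - 1e-12, , drop = FALSE]
  }
  list(ic_frame = i0 + st$ic - 1L, ic_mag = v_win[st$ic],
       to_frame = i0 + st$to - 1L, to_mag = v_win[st$to])
}
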
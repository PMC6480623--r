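# Local maxima with topographic prominence.
#
# A peak's prominence is its height above the higher of the two lowest
# points separating it from higher terrain (or from the series edge when no
# higher sample exists on that side). Strict local maxima only (plateau
# samples are not peaks), so window edges and constant stretches never
# produce candidates. Since prominence <= height - min(x), peaks failing
# that bound are discarded before the exact (walking) computation; this is
# the hot path of the sliding-window engine.
find_prominent_peaks <- function(x, min_prominence = 0) {
  n <- length(x)
  empty <- list(idx = integer(), height = numeric(), prominence = numeric())
  if (n < 3L) return(empty)
  mid <- x[2:(n - 1L)]
  idx <- which(mid > x[1:(n - 2L)] & mid >= x[3:n]) + 1L
  # drop the later sample of tied neighbouring maxima (flat-top pair)
  if (length(idx) > 1L) idx <- idx[c(TRUE, diff(idx) > 1L)]
  if (!length(idx)) return(empty)
  xmin <- min(x)
  cand <- idx[x[idx] - xmin >= min_prominence]
  if (!length(cand)) return(empty)
  prom <- vapply(cand, function(i) {
    h <- x[i]
    lmin <- h
    j <- i
    while (j > 1L) {
      j <- j - 1L
      if (x[j] > h) break
      if (x[j] < lmin) lmin <- x[j]
    }
    rmin <- h
    j <- i
    while (j < n) {
      j <- j + 1L
      if (x[j] > h) break
      if (x[j] < rmin) rmin <- x[j]
    }
    h - max(lmin, rmin)
  }, numeric(1))
  keep <- prom >= min_prominence & prom > 0
  list(idx = cand[keep], height = x[cand[keep]], prominence = prom[keep])
}

# Adaptive prominence floor for a window: k times the MAD-based spread
# (robust to the impact peaks that would inflate an SD), with a
# scale-invariant floor at 10% of the window's range so that filter ringing
# lobes and numerical ripple on a near-constant window are never admitted.
# No absolute g threshold is involved, so candidate times are invariant to
# positive rescaling of the window.
adaptive_prominence <- function(x, k = 1.0) {
  max(k * stats::mad(x), 0.1 * (max(x) - min(x)))
}
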
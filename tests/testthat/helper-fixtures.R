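# shared fixture builders; everything is generated in code at test time

# minimal constant-baseline foot trial with Gaussian impact bumps on VT
mk_foot_window <- function(peaks, fs = 200, dur = 2, amp = 8, width = 0.02,
                           dips = numeric(0), dip_amp = 3) {
  tt <- (seq_len(round(dur * fs)) - 1) / fs
  vt <- rep(1, length(tt))
  for (p in peaks) vt <- vt + amp * exp(-((tt - p) / width)^2)
  for (d in dips) vt <- vt - dip_amp * exp(-((tt - d) / width)^2)
  triaxial_trial(cbind(0, 0, vt), fs = fs, site = "foot")
}

mk_back_window <- function(peaks, fs = 200, dur = 2, amp = 2.4, width = 0.025,
                           dips = numeric(0), dip_amp = 1.5, ml = NULL) {
  tt <- (seq_len(round(dur * fs)) - 1) / fs
  vt <- rep(1, length(tt))
  for (p in peaks) vt <- vt + amp * exp(-((tt - p) / width)^2)
  for (d in dips) vt <- vt - dip_amp * exp(-((tt - d) / width)^2)
  m <- cbind(if (is.null(ml)) 0 else ml, 0, vt)
  tr <- triaxial_trial(m, fs = fs, site = "back", axis_map = c(ml = 1, ap = 2, vt = 3))
  tr$aligned <- TRUE  # constructed directly in the aligned frame
  tr
}

# brute-force oracle for the force detector: explicit sample-by-sample scan
# marking every up-crossing of ic_thr and, per loaded region, the last
# sample >= to_thr, then the 0.1 s rule and the IC-spacing rule.
force_oracle <- function(v, fs, ic_thr = 10, to_thr = 25, min_gap = 0.1,
                         min_sep = 0.25) {
  ic <- integer(0); to <- integer(0)
  inside <- FALSE
  start <- NA_integer_
  last25 <- NA_integer_
  flush <- function() {
    if (!is.na(start) && !is.na(last25) && (last25 - start) / fs >= min_gap - 1e-12) {
      ic <<- c(ic, start); to <<- c(to, last25)
    }
  }
  for (i in seq_along(v)) {
    if (!inside && v[i] >= ic_thr) {
      inside <- TRUE; start <- i; last25 <- NA_integer_
    }
    if (inside && v[i] >= to_thr) last25 <- i
    if (inside && v[i] < ic_thr) {
      flush(); inside <- FALSE; start <- NA_integer_; last25 <- NA_integer_
    }
  }
  if (inside) flush()
  if (length(ic) > 1 && min_sep > 0) {
    keep <- rep(TRUE, length(ic))
    last <- ic[1]
    for (i in 2:length(ic)) {
      if ((ic[i] - last) / fs < min_sep - 1e-12) keep[i] <- FALSE else last <- ic[i]
    }
    ic <- ic[keep]; to <- to[keep]
  }
  list(t_ic = (ic - 1) / fs, t_to = (to - 1) / fs)
}

# random piecewise vGRF-like signal: random stances of random height/length
random_vgrf <- function(fs = 500, dur = 3) {
  n <- round(dur * fs)
  v <- numeric(n)
  i <- 1 + sample.int(round(0.3 * fs), 1)
  while (i < n - 10) {
    len <- sample.int(round(0.35 * fs), 1) + 5L
    hi <- min(i + len, n)
    peak <- stats::runif(1, 5, 1500)   # some stances never reach 25 N or even 10 N
    u <- seq(0, 1, length.out = hi - i + 1)
    v[i:hi] <- peak * sin(pi * u)^0.5 + stats::rnorm(hi - i + 1, 0, 2)
    i <- hi + sample.int(round(0.4 * fs), 1) + 2L
  }
  pmax(0, v)
}

expect_tables_equal <- function(a, b) {
  expect_equal(as.data.frame(a), as.data.frame(b))
}
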
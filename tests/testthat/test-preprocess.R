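test_that("lowpass is zero-lag, preserves DC, and attenuates out-of-band power", {
  fs <- 200
  expect_equal(lowpass(rep(1, 400), fs), rep(1, 400), tolerance = 1e-9)

  # symmetric triangular pulse: zero-phase filtering keeps the peak index
  x <- c(rep(0, 180), seq(0, 1, length.out = 21), seq(1, 0, length.out = 21)[-1], rep(0, 180))
  y <- lowpass(x, fs)
  expect_equal(which.max(y), which.max(x))

  tt <- (0:(4 * fs - 1)) / fs
  mix <- sin(2 * pi * 2 * tt) + sin(2 * pi * 50 * tt)
  y <- lowpass(mix, fs)
  sp <- Mod(stats::fft(y))[1:(2 * fs)]
  f_axis <- (0:(2 * fs - 1)) / 4
  p50 <- sp[which.min(abs(f_axis - 50))]
  p2 <- sp[which.min(abs(f_axis - 2))]
  expect_lt(20 * log10(p50 / p2), -40)          # > 40 dB down at 50 Hz
  core <- y[(fs):(3 * fs)]
  expect_equal(max(abs(core)), 1, tolerance = 0.02)  # 2 Hz amplitude kept

  expect_error(lowpass(rnorm(10), fs), "too short")
  expect_error(lowpass(rnorm(400), fs, cutoff = 100), "Nyquist")
})

test_that("lowpass is near-idempotent for band-limited signals", {
  fs <- 200
  tt <- (0:(3 * fs - 1)) / fs
  x <- sin(2 * pi * 1 * tt)
  y1 <- lowpass(x, fs)
  y2 <- lowpass(y1, fs)
  expect_lt(sqrt(mean((y2 - y1)^2)) / sqrt(mean(y1^2)), 0.01)
})

test_that("gravity alignment rotates the mean vector onto +VT", {
  # raw back: constant 1 g on the raw sensor Y axis (VT) -> identity case
  raw <- matrix(rep(c(0, 1, 0), each = 400), 400, 3)
  tr <- triaxial_trial(raw, 200, "back")  # default back map: Y -> VT
  al <- align_back_to_gravity(tr)
  expect_true(al$aligned)
  expect_equal(unname(colMeans(al$samples)), c(0, 0, 1), tolerance = 1e-12)

  # constant 1 g vector tilted 10 degrees in the sagittal (AP-VT) plane
  th <- 10 * pi / 180
  m <- cbind(ML = 0, AP = sin(th), VT = cos(th))[rep(1, 300), ]
  tr2 <- triaxial_trial(m, 200, "back", axis_map = c(ml = 1, ap = 2, vt = 3))
  tr2$aligned <- TRUE   # already in the aligned axis convention: no AP flip
  al2 <- align_back_to_gravity(tr2)
  expect_equal(unname(al2$samples[1, ]), c(0, 0, 1), tolerance = 1e-9)

  # raw-convention equivalent: AP flip plus rotation must agree
  raw3 <- cbind(0, cos(th), -sin(th))[rep(1, 300), ]  # X=ML, Y=VT, Z=AP_post
  al3 <- align_back_to_gravity(triaxial_trial(raw3, 200, "back"))
  expect_equal(unname(al3$samples[1, ]), c(0, 0, 1), tolerance = 1e-9)

  expect_error(align_back_to_gravity(triaxial_trial(matrix(0.05, 10, 3), 200, "back")),
               "outside")
  expect_error(align_back_to_gravity(triaxial_trial(raw, 200, "foot")), "back")
})

test_that("aligning an already-aligned trial is a no-op", {
  sim <- simulate_trial(gait_sim_spec(duration = 5, noise_sd = 0.02, seed = 11))
  al <- align_back_to_gravity(sim$back)
  al2 <- align_back_to_gravity(al)
  expect_equal(al2$samples, al$samples, tolerance = 1e-9)
})

test_that("alignment recovers a known sagittal tilt in simulated data", {
  sim <- simulate_trial(gait_sim_spec(duration = 10, noise_sd = 0, seed = 5))
  al <- align_back_to_gravity(sim$back)
  g <- colMeans(al$samples)
  expect_equal(unname(g[1:2] / sqrt(sum(g^2))), c(0, 0), tolerance = 1e-3)
  # ML side pulses survive with their sign: right steps positive
  tru <- steps(sim$truth)
  i_r <- round(tru$t_ic[tru$side == "right"] * al$fs) + 1
  i_l <- round(tru$t_ic[tru$side == "left"] * al$fs) + 1
  expect_true(all(al$samples[i_r, "ML"] > 0.1))
  expect_true(all(al$samples[i_l, "ML"] < -0.1))
})

test_that("trimming arithmetic matches the treadmill and overground protocols", {
  tr <- triaxial_trial(matrix(rnorm(18000 * 3), 18000, 3), fs = 200, site = "foot")
  tm <- trim_trial(tr, "seconds", 15)           # 90 s -> 60 s
  expect_equal(n_samples(tm), 12000)
  expect_equal(duration(tm), 60)

  tr2 <- force_trial(abs(rnorm(1000, 300, 50)), fs = 100)
  tf <- trim_trial(tr2, "fraction", 0.05)       # 5% per end
  expect_equal(n_samples(tf), 900)

  expect_equal(trim_trial(tr, "seconds", 0)$samples, tr$samples)
  expect_error(trim_trial(tr2, "seconds", 10), "consume")
  expect_error(trim_trial(tr2, "fraction", 0.6), "fraction")
})

test_that("trims in seconds compose additively on the sample grid", {
  tr <- force_trial(abs(rnorm(4000, 300, 50)), fs = 200)
  a <- 1.5; b <- 2.0
  two <- trim_trial(trim_trial(tr, "seconds", a), "seconds", b)
  one <- trim_trial(tr, "seconds", a + b)
  expect_equal(two$vgrf, one$vgrf)
})
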
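test_that("window count arithmetic matches the sliding grid", {
  tr <- force_trial(abs(rnorm(10 * 1000, 50, 10)), fs = 1000)
  tr <- resample_trial(tr, 200)
  pool <- collect_candidates(tr, "force", window_params(200, 2, 1))
  expect_equal(pool$n_windows, 9)            # 10 s trial, 2 s window, 1 s shift
  # non-overlapping grid: pool equals the union of disjoint windows
  sim <- simulate_trial(gait_sim_spec(duration = 8, noise_sd = 0, seed = 4))
  foot <- lowpass_trial(sim$foot)
  p1 <- collect_candidates(foot, "foot", window_params(200, 2, 2))
  manual <- lapply(seq(0, 6, by = 2), function(s) {
    idx <- (s * 200 + 1):((s + 2) * 200)
    w <- foot; w$samples <- w$samples[idx, , drop = FALSE]
    foot_candidates(w, t0 = s)
  })
  man_ic <- sort(unique(unlist(lapply(manual, function(m) m$ic$frame))))
  expect_identical(p1$ic$frame, man_ic)
})

test_that("candidate pools are unique and sorted by frame", {
  sim <- simulate_trial(gait_sim_spec(duration = 6, noise_sd = 0.05, seed = 8))
  pool <- collect_candidates(lowpass_trial(sim$foot), "foot", window_params())
  expect_false(any(duplicated(pool$ic$frame)))
  expect_false(any(duplicated(pool$to$frame)))
  expect_true(all(diff(pool$ic$frame) > 0))
  expect_true(all(pool$ic$t >= 0 & pool$ic$t <= duration(sim$foot)))
})

test_that("with default overlap every ground-truth event reaches the pool", {
  sim <- simulate_trial(gait_sim_spec(duration = 10, noise_sd = 0.05, seed = 12))
  tru <- steps(sim$truth)
  foot <- lowpass_trial(sim$foot)
  pool <- collect_candidates(foot, "foot", window_params())
  for (t0 in tru$t_ic[tru$side == "right"]) {
    expect_lte(min(abs(pool$ic$t - t0)), 0.015)
  }
})

test_that("consolidation applies the magnitude rule under the cadence bounds", {
  mk_pool <- function(ic_t, ic_m, to_t = numeric(0), to_m = numeric(0), fs = 200) {
    structure(list(
      ic = data.frame(frame = round(ic_t * fs), t = ic_t, magnitude = ic_m),
      to = data.frame(frame = round(to_t * fs), t = to_t, magnitude = to_m),
      fs = fs, duration = 10), class = "candidate_pool")
  }
  # two back ICs 0.1 s apart, both cadence-viable: greater magnitude wins
  p <- mk_pool(c(1.0, 1.1), c(1.8, 2.3))
  tab <- consolidate(p, back_config(), source = "back")
  expect_equal(tab$t[tab$kind == "IC"], 1.1)
  expect_equal(tab$magnitude[tab$kind == "IC"], 2.3)
  # equal magnitudes: the earlier is retained
  p2 <- mk_pool(c(1.0, 1.1), c(2.0, 2.0))
  tab2 <- consolidate(p2, back_config(), source = "back")
  expect_equal(tab2$t[tab2$kind == "IC"], 1.0)
  # single IC with TOs at +0.05 and +0.30 s: the 0.1 s floor drops the first
  p3 <- mk_pool(1.0, 2.0, to_t = c(1.05, 1.30), to_m = c(3, 1))
  st3 <- steps(consolidate(p3, back_config(), source = "back"))
  expect_equal(st3$t_to, 1.30)
  # viability: conflicting pair where only the second fits the previous IC
  p4 <- mk_pool(c(1.0, 1.15, 1.30), c(5, 1, 4))
  tab4 <- consolidate(p4, back_config(), source = "back")
  expect_equal(tab4$t[tab4$kind == "IC"], c(1.0, 1.30))
})

test_that("consolidating ground-truth-only pools is a fixed point", {
  sim <- simulate_trial(gait_sim_spec(duration = 10, noise_sd = 0, seed = 19))
  tru <- steps(sim$truth)
  fs <- 200
  pool <- structure(list(
    ic = data.frame(frame = round(tru$t_ic * fs), t = tru$t_ic, magnitude = 2),
    to = data.frame(frame = round(tru$t_to * fs), t = tru$t_to, magnitude = 1.5),
    fs = fs, duration = 10), class = "candidate_pool")
  tab <- consolidate(pool, back_config(), source = "back")
  st <- steps(tab)
  expect_equal(st$t_ic, tru$t_ic)
  expect_equal(st$t_to, tru$t_to)
})

test_that("consolidation is idempotent and its output satisfies all invariants", {
  withr::local_seed(99)
  fs <- 200
  for (rep in 1:60) {
    n_ic <- sample(2:40, 1)
    ic_t <- sort(round(runif(n_ic, 0.2, 19.8) * fs)) / fs
    ic_t <- ic_t[!duplicated(ic_t)]
    n_to <- sample(2:40, 1)
    to_t <- sort(round(runif(n_to, 0.2, 19.8) * fs)) / fs
    to_t <- to_t[!duplicated(to_t)]
    cfg <- if (rep %% 2) back_config() else foot_config()
    src <- if (rep %% 2) "back" else "foot"
    pool <- structure(list(
      ic = data.frame(frame = round(ic_t * fs), t = ic_t,
                      magnitude = runif(length(ic_t), 0.5, 8)),
      to = data.frame(frame = round(to_t * fs), t = to_t,
                      magnitude = runif(length(to_t), 0.2, 4)),
      fs = fs, duration = 20), class = "candidate_pool")
    tab <- consolidate(pool, cfg, source = src)
    expect_silent(validate_event_table(tab))
    st <- steps(tab)
    ic <- st$t_ic
    if (length(ic) > 1) expect_true(all(diff(ic) >= cfg$min_ic_separation - 1e-9))
    ok <- !is.na(st$t_to)
    expect_true(all(st$t_to[ok] >= st$t_ic[ok] + 0.1 - 1e-9))
    if (any(ok)) expect_equal(st$gct[ok], st$t_to[ok] - st$t_ic[ok])
    nxt <- c(ic[-1], Inf)
    expect_true(all(st$t_to[ok] < nxt[ok] + 1e-9))
    # idempotence: re-consolidate the consolidated output
    pool2 <- structure(list(
      ic = data.frame(frame = round(ic * fs), t = ic, magnitude = st$mag_ic),
      to = data.frame(frame = round(st$t_to[ok] * fs), t = st$t_to[ok],
                      magnitude = st$mag_to[ok]),
      fs = fs, duration = 20), class = "candidate_pool")
    tab2 <- consolidate(pool2, cfg, source = src)
    expect_equal(steps(tab2)$t_ic, ic)
    expect_equal(steps(tab2)$t_to, st$t_to)
  }
})

test_that("detect_trial runs the full pipeline per site", {
  sim <- simulate_trial(gait_sim_spec(duration = 8, noise_sd = 0.05, seed = 27))
  tru <- steps(sim$truth)
  ef <- detect_trial(sim$foot)
  expect_equal(nrow(steps(ef)), sum(tru$side == "right"))
  expect_true(all(ef$source == "foot"))
  eb <- detect_trial(sim$back)
  expect_equal(nrow(steps(eb)), nrow(tru))
  expect_true(all(eb$side %in% c("left", "right")))
  short <- triaxial_trial(matrix(1, 80, 3), 200, "foot")
  expect_warning(e0 <- detect_trial(short), "shorter than 1 s")
  expect_equal(nrow(e0), 0)
})

test_that("output-rate emulation responds to the window shift", {
  sim <- simulate_trial(gait_sim_spec(duration = 5, noise_sd = 0.02, seed = 31))
  slow <- measure_output_rate(sim$foot, window_params(200, 1, 0.01))
  fast <- measure_output_rate(sim$foot, window_params(200, 1, 1))
  expect_true(all(slow$rates > 0))
  expect_gt(fast$mean, slow$mean)
  empty <- measure_output_rate(triaxial_trial(matrix(1, 80, 3), 200, "foot"))
  expect_equal(length(empty$rates), 0)
})
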
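mk_table <- function(t_ic, gct = 0.25, side = "unknown", source = "force", fs = 200) {
  n <- length(t_ic)
  event_table(kind = rep(c("IC", "TO"), each = n), t = c(t_ic, t_ic + gct),
              side = rep(rep_len(side, n), 2), magnitude = 1, source = source,
              step = rep(seq_len(n), 2), fs = fs)
}

test_that("identical tables match perfectly and give zero differences", {
  a <- mk_table(c(1, 1.4, 1.8, 2.2))
  m <- match_events(a, a)
  expect_equal(nrow(m$pairs), 4)
  expect_equal(m$skipped_a, 0)
  expect_equal(m$skipped_b, 0)
  d <- differences(m)
  expect_equal(d$stats$mean, c(0, 0, 0))
})

test_that("a missing middle step is a skipped step for the deficient method", {
  a <- mk_table(c(1, 1.4, 1.8, 2.2))
  b <- mk_table(c(1, 1.4, 2.2))
  m <- match_events(a, b)
  expect_equal(m$skipped_a, 1)   # the step b missed exists only in a
  expect_equal(m$skipped_b, 0)
  expect_equal(nrow(m$pairs), 3)
  expect_error(match_events(a, b, tol = 0), "tol")
})

test_that("right-only comparisons drop left steps without counting them as skips", {
  back <- mk_table(seq(1, 3.8, by = 0.35), side = rep(c("right", "left"), 5),
                   source = "back")
  foot <- mk_table(seq(1, 3.8, by = 0.70) + 0.01, source = "foot")  # right steps only
  m <- match_events(back, foot, right_only = TRUE)
  expect_equal(nrow(m$pairs), 5)
  expect_equal(m$skipped_a, 0)   # 5 left back steps were excluded, not skipped
  expect_equal(m$skipped_b, 0)
  expect_equal(m$side_mismatches, 0)
  # a back step labelled left that matches a foot step counts as a wrong side
  back2 <- back
  back2$side[back2$step == 3] <- "left"
  back2$side[back2$step == 4] <- "right"   # keep alternation plausible
  m2 <- match_events(back2, foot, right_only = TRUE)
  expect_equal(m2$side_mismatches, 0)      # that step no longer enters (left-filtered)
  full <- match_events(back2, inherit_sides(mk_table(seq(1, 3.8, by = 0.35)),
                                            back), tol = 0.25)
  expect_equal(full$side_mismatches, 2)    # both relabelled steps disagree
})

test_that("difference statistics match the closed form", {
  a <- mk_table(c(1, 2, 3) + c(0.01, 0.02, 0.03))
  b <- mk_table(c(1, 2, 3))
  d <- differences(match_events(a, b))
  ic <- d$stats[d$stats$quantity == "IC", ]
  expect_equal(ic$mean, 0.02, tolerance = 1e-12)
  expect_equal(ic$sd, 0.01, tolerance = 1e-12)
  expect_equal(ic$loa_lower, 0.02 - 1.96 * 0.01, tolerance = 1e-12)
  expect_equal(ic$loa_upper, 0.02 + 1.96 * 0.01, tolerance = 1e-12)
  # all-equal differences collapse the LoA onto the mean
  a2 <- mk_table(c(1, 2, 3) + 0.05)
  d2 <- differences(match_events(a2, b))
  ic2 <- d2$stats[d2$stats$quantity == "IC", ]
  expect_equal(ic2$sd, 0)
  expect_equal(ic2$loa_lower, ic2$loa_upper)
  # GCT difference is TO difference minus IC difference per matched step
  expect_equal(d$gct_d, d$to_d - d$ic_d)
})

test_that("differences are antisymmetric under operand swap", {
  withr::local_seed(5)
  a <- mk_table(sort(runif(8, 1, 9)) + seq(0, 2.8, by = 0.4))
  b <- mk_table(steps(a)$t_ic + rnorm(8, 0, 0.02), gct = 0.27)
  dab <- differences(match_events(a, b))
  dba <- differences(match_events(b, a))
  expect_equal(dab$ic_d, -dba$ic_d)
  expect_equal(dab$to_d, -dba$to_d)
  expect_equal(dab$gct_d, -dba$gct_d)
})

test_that("fewer than two pairs leaves SD and LoA undefined", {
  a <- mk_table(1)
  d <- differences(match_events(a, a))
  expect_equal(d$stats$mean, c(0, 0, 0))
  expect_true(all(is.na(d$stats$sd)))
  expect_true(all(is.na(d$stats$loa_lower)))
})

test_that("condition summaries pool difference arrays before summarising", {
  r1 <- structure(list(ic_d = 0.01, to_d = numeric(0)), class = "agreement_report")
  r2 <- structure(list(ic_d = 0.03, to_d = numeric(0)), class = "agreement_report")
  out <- condition_summary(list(r1, r2), c("track", "track"))
  expect_equal(out$mean[out$event == "IC"], 0.02)
  one <- condition_summary(list(r1), "solo")
  expect_equal(one$mean[one$event == "IC"], 0.01)
  r0 <- structure(list(ic_d = numeric(0), to_d = numeric(0)), class = "agreement_report")
  expect_warning(res <- condition_summary(list(r1, r0), c("a", "b")), "omitted")
  expect_equal(unique(res$condition), "a")
})
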
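#' Match steps between two event tables
#'
#' Greedy nearest-neighbour matching of initial contacts within `+/- tol`
#' seconds (ties to the earlier candidate pair); each TO inherits its IC's
#' pairing. A step present in one table with no counterpart in the other is
#' a skipped step for the deficient method. Provisional (trial-edge) events
#' are excluded before matching. With `right_only = TRUE` (required whenever
#' the foot method - which records right steps only - is one operand),
#' left-sided steps are removed from both tables before matching, so they
#' are never counted as skips; events with unknown side are kept.
#'
#' @param table_a,table_b [event_table()] objects (differences are reported
#'   as A minus B).
#' @param tol matching tolerance, s (> 0). The default 0.25 s is half the
#'   minimum contralateral step interval, guaranteeing unambiguous
#'   assignment at cadences of 120-240 steps/min.
#' @param right_only drop left-sided steps before matching.
#' @return an object of class `matched_steps`: list with `pairs` (data frame
#'   of matched IC/TO times and sides), `skipped_a`, `skipped_b`,
#'   `side_mismatches` (matched pairs whose sided event is not labelled
#'   right when `right_only`, or whose sides disagree otherwise), `n_a`,
#'   `n_b`.
#' @export
match_events <- function(table_a, table_b, tol = 0.25, right_only = FALSE) {
  stopifnot(inherits(table_a, "event_table"), inherits(table_b, "event_table"))
  if (tol <= 0) stop("tol must be > 0")
  sa <- steps(table_a); sb <- steps(table_b)
  sa <- sa[!sa$provisional, , drop = FALSE]
  sb <- sb[!sb$provisional, , drop = FALSE]
  if (right_only) {
    sa <- sa[sa$side != "left", , drop = FALSE]
    sb <- sb[sb$side != "left", , drop = FALSE]
  }
  na <- nrow(sa); nb <- nrow(sb)
  if (na && nb) {
    cand <- expand.grid(i = seq_len(na), j = seq_len(nb))
    cand$d <- abs(sa$t_ic[cand$i] - sb$t_ic[cand$j])
    cand <- cand[cand$d <= tol, , drop = FALSE]
    cand <- cand[order(cand$d, sa$t_ic[cand$i]), , drop = FALSE]
    used_a <- logical(na); used_b <- logical(nb)
    pi <- integer(0); pj <- integer(0)
    for (r in seq_len(nrow(cand))) {
      i <- cand$i[r]; j <- cand$j[r]
      if (!used_a[i] && !used_b[j]) {
        used_a[i] <- TRUE; used_b[j] <- TRUE
        pi <- c(pi, i); pj <- c(pj, j)
      }
    }
    o <- order(sa$t_ic[pi])
    pi <- pi[o]; pj <- pj[o]
  } else {
    pi <- pj <- integer(0)
  }
  pairs <- data.frame(
    t_ic_a = sa$t_ic[pi], t_ic_b = sb$t_ic[pj],
    t_to_a = sa$t_to[pi], t_to_b = sb$t_to[pj],
    side_a = sa$side[pi], side_b = sb$side[pj],
    stringsAsFactors = FALSE
  )
  mism <- if (right_only) {
    sided <- ifelse(pairs$side_a == "unknown", pairs$side_b, pairs$side_a)
    sum(sided != "unknown" & sided != "right")
  } else {
    sum(pairs$side_a != "unknown" & pairs$side_b != "unknown" &
          pairs$side_a != pairs$side_b)
  }
  structure(list(pairs = pairs,
                 skipped_a = na - length(pi), skipped_b = nb - length(pj),
                 side_mismatches = mism, n_a = na, n_b = nb,
                 sources = c(a = table_a$source[1], b = table_b$source[1])),
            class = "matched_steps")
}

#' @export
print.matched_steps <- function(x, ...) {
  cat(sprintf("<matched_steps> %d pairs (%s vs %s); skipped: a=%d b=%d; wrong sides=%d\n",
              nrow(x$pairs), x$sources["a"], x$sources["b"],
              x$skipped_a, x$skipped_b, x$side_mismatches))
  invisible(x)
}

#' Timing differences and Bland-Altman agreement
#'
#' Signed per-step differences (method A minus method B) for IC, TO and
#' ground contact time (GCT = TO - IC, so GCT difference = TO difference -
#' IC difference per matched step), with mean, SD and 95% limits of
#' agreement (mean +/- 1.96 SD) per quantity. TO and GCT use only pairs
#' where both methods produced a TO. With fewer than 2 pairs the mean is
#' reported and SD/LoA are NA.
#'
#' @param matched a [match_events()] result.
#' @return an object of class `agreement_report`: list with per-quantity
#'   difference arrays (`ic_d`, `to_d`, `gct_d`), mid-times for plotting,
#'   and a `stats` data frame (`quantity`, `n`, `mean`, `sd`, `loa_lower`,
#'   `loa_upper`).
#' @export
differences <- function(matched) {
  stopifnot(inherits(matched, "matched_steps"))
  p <- matched$pairs
  ic_d <- p$t_ic_a - p$t_ic_b
  both <- !is.na(p$t_to_a) & !is.na(p$t_to_b)
  to_d <- p$t_to_a[both] - p$t_to_b[both]
  gct_d <- to_d - ic_d[both]
  one <- function(q, d) {
    n <- length(d)
    m <- if (n) mean(d) else NA_real_
    s <- if (n >= 2) stats::sd(d) else NA_real_
    data.frame(quantity = q, n = n, mean = m, sd = s,
               loa_lower = m - 1.96 * s, loa_upper = m + 1.96 * s,
               stringsAsFactors = FALSE)
  }
  structure(list(
    ic_d = ic_d, to_d = to_d, gct_d = gct_d,
    ic_mid = (p$t_ic_a + p$t_ic_b) / 2,
    to_mid = (p$t_to_a[both] + p$t_to_b[both]) / 2,
    stats = rbind(one("IC", ic_d), one("TO", to_d), one("GCT", gct_d)),
    sources = matched$sources,
    skipped_a = matched$skipped_a, skipped_b = matched$skipped_b,
    side_mismatches = matched$side_mismatches
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> %s minus %s\n", x$sources["a"], x$sources["b"]))
  print(x$stats, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Bland-Altman plot of an agreement report
#'
#' Differences against the two-method mean event time per step, with the
#' mean difference and 95% limits of agreement drawn as horizontal lines.
#'
#' @param x an [differences()] report.
#' @param quantity `"IC"`, `"TO"` or `"GCT"`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.agreement_report <- function(x, quantity = c("IC", "TO", "GCT"), ...) {
  quantity <- match.arg(quantity)
  d <- switch(quantity, IC = x$ic_d, TO = x$to_d, GCT = x$gct_d)
  mid <- switch(quantity, IC = x$ic_mid, TO = x$to_mid, GCT = x$to_mid)
  st <- x$stats[x$stats$quantity == quantity, ]
  graphics::plot(mid, d, xlab = "mean event time (s)",
                 ylab = sprintf("%s difference, %s - %s (s)", quantity,
                                x$sources["a"], x$sources["b"]), ...)
  graphics::abline(h = c(st$mean, st$loa_lower, st$loa_upper),
                   lty = c(1, 2, 2))
  invisible(x)
}

#' Per-condition summary of method differences
#'
#' Pools the per-step difference arrays of all trials sharing a condition
#' label before computing the mean and SD (pooling first, then summarising,
#' matching the per-participant/per-trial-type protocol), for IC and TO
#' separately. Empty groups are omitted with a warning.
#'
#' @param reports list of [differences()] reports (one per trial).
#' @param conditions character vector of condition labels, one per report.
#' @return data frame with `condition`, `event`, `n`, `mean`, `sd`.
#' @export
condition_summary <- function(reports, conditions) {
  stopifnot(length(reports) == length(conditions))
  out <- list()
  for (cond in unique(conditions)) {
    idx <- which(conditions == cond)
    ic <- unlist(lapply(reports[idx], `[[`, "ic_d"))
    to <- unlist(lapply(reports[idx], `[[`, "to_d"))
    if (!length(ic) && !length(to)) {
      warning("condition '", cond, "' has no matched steps; omitted")
      next
    }
    out[[length(out) + 1L]] <- data.frame(
      condition = cond, event = c("IC", "TO"),
      n = c(length(ic), length(to)),
      mean = c(mean(ic), mean(to)),
      sd = c(stats::sd(ic), stats::sd(to)),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}
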
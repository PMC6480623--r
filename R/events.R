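#' Construct a gait event table
#'
#' An event table is a data frame of time-ordered IC (initial contact) and
#' TO (toe off) events with columns `kind`, `t` (s from trial start), `side`
#' (`"left"`, `"right"` or `"unknown"`), `magnitude` (the signal value used
#' for candidate consolidation: resultant g for foot IC, VT g for back IC,
#' -VT g for TO, N for force events), `source`, `step` (integer pairing id:
#' an IC and its TO share a step id) and `provisional` (event within 0.1 s
#' of a trial edge; excluded from method comparisons).
#'
#' @param kind character vector, `"IC"` or `"TO"`.
#' @param t event times in seconds (>= 0).
#' @param side,magnitude,source,step,provisional per-event fields (recycled).
#' @param fs sampling rate of the originating trial (Hz).
#' @param validate check the table invariants (default `TRUE`).
#' @return an object of classes `event_table` and `data.frame`.
#' @export
event_table <- function(kind = character(), t = numeric(), side = "unknown",
                        magnitude = NA_real_, source = "force", step = NA_integer_,
                        provisional = FALSE, fs = NA_real_, validate = TRUE) {
  n <- length(kind)
  df <- data.frame(kind = as.character(kind), t = as.numeric(t),
                   side = rep_len(as.character(side), n),
                   magnitude = rep_len(as.numeric(magnitude), n),
                   source = rep_len(as.character(source), n),
                   step = rep_len(as.integer(step), n),
                   provisional = rep_len(as.logical(provisional), n),
                   stringsAsFactors = FALSE)
  df <- df[order(df$t, df$kind), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "fs") <- fs
  class(df) <- c("event_table", "data.frame")
  if (validate) validate_event_table(df)
  df
}

#' Validate event table invariants
#'
#' Checks: known kinds/sides/sources, finite non-negative times and finite
#' magnitudes, strictly increasing times within each kind, every TO paired
#' to exactly one preceding IC with TO >= IC + 0.1 s, and the cadence floor
#' on consecutive ICs (>= 0.5 s for the ipsilateral foot source, >= 0.25 s
#' otherwise).
#'
#' @param x an `event_table`.
#' @param min_ic_to_gap minimum IC-to-TO gap in seconds.
#' @return `x`, invisibly; errors on violation.
#' @export
validate_event_table <- function(x, min_ic_to_gap = 0.1) {
  stopifnot(inherits(x, "event_table"))
  if (!all(x$kind %in% c("IC", "TO"))) stop("kind must be 'IC' or 'TO'")
  if (!all(x$side %in% c("left", "right", "unknown"))) stop("invalid side label")
  if (!all(x$source %in% c("force", "foot", "back", "truth"))) stop("invalid source")
  if (any(!is.finite(x$t)) || any(x$t < 0)) stop("event times must be finite and >= 0")
  if (any(!is.finite(x$magnitude) & !is.na(x$magnitude))) stop("magnitudes must be finite")
  for (k in c("IC", "TO")) {
    tt <- x$t[x$kind == k]
    if (length(tt) > 1L && any(diff(tt) <= 0)) {
      stop("event times must be strictly increasing within kind ", k)
    }
  }
  st <- steps(x)
  if (any(!is.na(st$t_to) & st$t_to < st$t_ic + min_ic_to_gap - 1e-9)) {
    stop("a TO occurs earlier than ", min_ic_to_gap, " s after its IC")
  }
  to_step <- x$step[x$kind == "TO"]
  if (anyNA(to_step) || anyDuplicated(to_step)) {
    stop("each TO must be paired to exactly one IC")
  }
  if (!all(to_step %in% x$step[x$kind == "IC"])) stop("orphan TO event")
  ic_t <- x$t[x$kind == "IC"]
  src <- unique(x$source)
  if (length(ic_t) > 1L && length(src) == 1L) {
    floor_s <- if (src == "foot") 0.5 else 0.25
    if (any(diff(ic_t) < floor_s - 1e-9)) {
      stop("consecutive ICs closer than the ", floor_s, " s cadence floor")
    }
  }
  invisible(x)
}

#' Paired step view of an event table
#'
#' @param x an `event_table`.
#' @return a data frame with one row per step: `step`, `side`, `t_ic`,
#'   `t_to` (NA for IC-only steps), `gct` (= t_to - t_ic), `mag_ic`,
#'   `mag_to`, `provisional` (TRUE if either event is provisional).
#' @export
steps <- function(x) {
  ic <- x[x$kind == "IC", , drop = FALSE]
  to <- x[x$kind == "TO", , drop = FALSE]
  j <- match(ic$step, to$step)
  out <- data.frame(step = ic$step, side = ic$side, t_ic = ic$t,
                    t_to = to$t[j], mag_ic = ic$magnitude, mag_to = to$magnitude[j],
                    provisional = ic$provisional | ifelse(is.na(j), FALSE, to$provisional[j]),
                    stringsAsFactors = FALSE)
  out$gct <- out$t_to - out$t_ic
  out[order(out$t_ic), c("step", "side", "t_ic", "t_to", "gct",
                         "mag_ic", "mag_to", "provisional")]
}

#' @export
print.event_table <- function(x, ...) {
  st <- steps(x)
  cat(sprintf("<event_table> source=%s  %d IC, %d TO (%d IC-only)\n",
              paste(unique(x$source), collapse = "/"),
              sum(x$kind == "IC"), sum(x$kind == "TO"), sum(is.na(st$t_to))))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("... ", nrow(x) - 10, " more events\n")
  invisible(x)
}

#' @export
summary.event_table <- function(object, ...) {
  st <- steps(object)
  cat(sprintf("%d steps; median cadence %.1f steps/min; median GCT %.3f s\n",
              nrow(st),
              if (nrow(st) > 1) 60 / stats::median(diff(st$t_ic)) else NA,
              stats::median(st$gct, na.rm = TRUE)))
  invisible(st)
}

#' Write / read an event table as CSV
#'
#' One row per event with header `kind,t,side,magnitude,source` (plus
#' `step`,`provisional`); times are written with 6 decimals and the pair
#' round-trips losslessly at that precision.
#'
#' @param table an `event_table`.
#' @param path file path.
#' @return `write_events_csv()`: `path` invisibly; `read_events_csv()`: an
#'   `event_table`.
#' @export
write_events_csv <- function(table, path) {
  stopifnot(inherits(table, "event_table"))
  df <- as.data.frame(table)
  df$t <- sprintf("%.6f", df$t)
  df$magnitude <- sprintf("%.6f", df$magnitude)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @param fs sampling rate to attach to the table (Hz).
#' @export
read_events_csv <- function(path, fs = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("kind", "t", "side", "magnitude", "source")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  event_table(kind = df$kind, t = df$t, side = df$side, magnitude = df$magnitude,
              source = df$source,
              step = if ("step" %in% names(df)) df$step else NA_integer_,
              provisional = if ("provisional" %in% names(df)) df$provisional else FALSE,
              fs = fs)
}
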
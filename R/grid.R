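#' Run the parameter-optimization grid
#'
#' For every combination of sampling rate, window size and change in window
#' start time, detects events from the foot, back and force signals of each
#' trial and scores the accelerometer methods against the force method:
#' skipped steps (per method, summed over trials), wrong step sides from the
#' back-foot comparison, and mean IC/TO/GCT differences for foot-force and
#' back-force. The default grid is 3 sampling rates x 3 window sizes x 6
#' shifts = 54 cells, one result row per cell.
#'
#' @param trials list of simulated (or loaded) trial triplets, each with
#'   elements `foot`, `back`, `force` (as returned by [simulate_trial()] /
#'   [simulate_cohort()]).
#' @param fs_grid,window_grid,shift_grid grid values (Hz, s, s).
#' @param tol matching tolerance passed to [match_events()].
#' @param measure_rate also time the engine per cell (hardware-dependent;
#'   default off).
#' @return data frame with one row per cell: the three parameters, step
#'   counts, skipped steps per method, wrong sides, and mean differences
#'   `ic_foot_force`, `to_foot_force`, `gct_foot_force`, `ic_back_force`,
#'   `to_back_force`, `gct_back_force` (s).
#' @export
grid_run <- function(trials, fs_grid = c(50, 100, 200), window_grid = c(1, 2, 5),
                     shift_grid = c(0.005, 0.01, 0.02, 0.1, 0.5, 1),
                     tol = 0.25, measure_rate = FALSE) {
  if (!length(fs_grid) || !length(window_grid) || !length(shift_grid)) {
    stop("empty parameter grid")
  }
  if (!is.null(trials$foot)) trials <- list(trials)  # single triplet
  cells <- expand.grid(fs = fs_grid, window_size = window_grid,
                       shift = shift_grid, KEEP.OUT.ATTRS = FALSE)
  cells <- cells[order(cells$fs, cells$window_size, cells$shift), , drop = FALSE]
  rows <- lapply(seq_len(nrow(cells)), function(r) {
    params <- window_params(cells$fs[r], cells$window_size[r], cells$shift[r])
    agg <- list(ff = list(), bf = list())
    skipped <- c(force = 0, foot = 0, back = 0)
    wrong <- 0L; n_steps <- 0L
    rate <- c(force = NA_real_, foot = NA_real_, back = NA_real_)
    for (tr in trials) {
      ev <- list(force = detect_trial(tr$force, params),
                 foot = detect_trial(tr$foot, params),
                 back = detect_trial(tr$back, params))
      # force events carry no side; inherit it from the simulator ground
      # truth so that right-only comparisons are meaningful
      if (!is.null(tr$truth)) ev$force <- inherit_sides(ev$force, tr$truth, tol)
      mf <- match_events(ev$foot, ev$force, tol = tol, right_only = TRUE)
      mb <- match_events(ev$back, ev$force, tol = tol)
      mbf <- match_events(ev$back, ev$foot, tol = tol, right_only = TRUE)
      # a skipped step belongs to the method that missed it: an unmatched
      # force step was skipped by the accelerometer method, and vice versa
      skipped <- skipped + c(force = mb$skipped_a, foot = mf$skipped_b,
                             back = mb$skipped_b)
      wrong <- wrong + mbf$side_mismatches
      n_steps <- n_steps + mb$n_b
      agg$ff[[length(agg$ff) + 1L]] <- differences(mf)
      agg$bf[[length(agg$bf) + 1L]] <- differences(mb)
    }
    pool_mean <- function(reps, fld) {
      v <- unlist(lapply(reps, `[[`, fld))
      if (length(v)) mean(v) else NA_real_
    }
    if (measure_rate) {
      tr <- trials[[1]]
      rate <- c(force = measure_output_rate(tr$force, params)$mean,
                foot = measure_output_rate(tr$foot, params)$mean,
                back = measure_output_rate(tr$back, params)$mean)
    }
    data.frame(fs = params$fs, window_size = params$window_size,
               shift = params$shift, n_steps = n_steps,
               skipped_force = skipped[["force"]],
               skipped_foot = skipped[["foot"]],
               skipped_back = skipped[["back"]],
               wrong_sides = wrong,
               ic_foot_force = pool_mean(agg$ff, "ic_d"),
               to_foot_force = pool_mean(agg$ff, "to_d"),
               gct_foot_force = pool_mean(agg$ff, "gct_d"),
               ic_back_force = pool_mean(agg$bf, "ic_d"),
               to_back_force = pool_mean(agg$bf, "to_d"),
               gct_back_force = pool_mean(agg$bf, "gct_d"),
               rate_force = rate[["force"]], rate_foot = rate[["foot"]],
               rate_back = rate[["back"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Copy side labels onto a sideless event table from a reference table
#'
#' Each IC (and its paired TO) takes the side of the nearest reference IC
#' within `tol` seconds; events with no reference neighbour stay unknown.
#'
#' @param table an [event_table()] (e.g. detected force events).
#' @param reference an [event_table()] with sides (e.g. simulator truth).
#' @param tol nearest-neighbour tolerance, s.
#' @return `table` with sides filled in.
#' @export
inherit_sides <- function(table, reference, tol = 0.25) {
  ric <- reference[reference$kind == "IC", , drop = FALSE]
  if (!nrow(ric) || !nrow(table)) return(table)
  ic_rows <- which(table$kind == "IC")
  for (i in ic_rows) {
    j <- which.min(abs(ric$t - table$t[i]))
    if (abs(ric$t[j] - table$t[i]) <= tol) table$side[i] <- ric$side[j]
  }
  to_rows <- which(table$kind == "TO")
  table$side[to_rows] <- table$side[ic_rows][match(table$step[to_rows],
                                                   table$step[ic_rows])]
  table
}

#' Render grid or agreement results as JSON and text
#'
#' Deterministic field ordering; output-rate columns are flagged
#' hardware-dependent in the text summary and are never part of pass/fail
#' logic. The JSON round-trips to the in-memory results.
#'
#' @param results a data frame ([grid_run()] output) or a list of summary
#'   values.
#' @param path optional file to write the JSON to.
#' @return list with `json` (character) and `text` (character vector, one
#'   summary line per row).
#' @export
report_render <- function(results, path = NULL) {
  json <- jsonlite::toJSON(results, dataframe = "rows", auto_unbox = TRUE,
                           digits = NA, na = "null", pretty = TRUE)
  text <- if (is.data.frame(results) && nrow(results)) {
    vapply(seq_len(nrow(results)), function(i) {
      r <- results[i, ]
      if (all(c("fs", "window_size", "shift") %in% names(r))) {
        sprintf(paste("fs=%g Hz window=%g s shift=%g s | steps=%s skipped(F/f/b)=%s/%s/%s",
                      "wrong sides=%s | mean IC foot-force=%s s back-force=%s s%s"),
                r$fs, r$window_size, r$shift, r$n_steps, r$skipped_force,
                r$skipped_foot, r$skipped_back, r$wrong_sides,
                format(r$ic_foot_force, digits = 3),
                format(r$ic_back_force, digits = 3),
                if (!is.na(r$rate_foot)) sprintf(" | output rate (hardware-dependent) foot=%.1f Hz", r$rate_foot) else "")
      } else paste(names(r), unlist(r), sep = "=", collapse = " ")
    }, character(1))
  } else character(0)
  if (!is.null(path)) writeLines(json, path)
  list(json = as.character(json), text = text)
}

#' Read and validate a run configuration file
#'
#' Single YAML file of flat `key: value` pairs; unknown keys are rejected
#' before any computation. Recognised keys mirror the detector, window and
#' trim settings (`filter.order`, `filter.cutoff_hz`, `trim.mode`,
#' `trim.amount`, `window.fs`, `window.size`, `window.shift`, and the
#' `foot.*` / `back.*` detector fields).
#'
#' @param path YAML file path.
#' @param extra additional permitted keys.
#' @return named list of settings.
#' @export
read_run_config <- function(path, extra = character()) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  allowed <- c("filter.order", "filter.cutoff_hz", "trim.mode", "trim.amount",
               "window.fs", "window.size", "window.shift",
               paste0("foot.", names(formals(foot_config))),
               paste0("back.", names(formals(back_config))),
               "compare.tol", "compare.right_only", extra)
  bad <- setdiff(names(cfg), allowed)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg
}
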
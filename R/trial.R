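#' Construct a tri-axial accelerometer trial
#'
#' A trial holds an N x 3 acceleration matrix in g with canonical column
#' order ML, AP, VT. Axis/sign conventions follow the sensor site: for the
#' foot sensor ML is + to the right, AP + posterior, VT + superior; for the
#' raw (unaligned) back sensor ML is + right, AP + posterior, VT + superior,
#' and after gravity alignment (see [align_back_to_gravity()]) AP points
#' anteriorly.
#'
#' @param samples numeric matrix (or data.frame) of accelerations, one row
#'   per sample. Columns are mapped to ML/AP/VT through `axis_map`.
#' @param fs sampling rate in Hz (> 0).
#' @param site `"foot"` or `"back"`.
#' @param axis_map named list/vector with entries `ml`, `ap`, `vt` giving the
#'   (1-based) input column carrying each axis; a negative index flips the
#'   sign of that column. Defaults: foot `c(ml=1, ap=2, vt=3)` (sensor X,Y,Z);
#'   back raw `c(ml=1, ap=3, vt=2)` (sensor X,Z,Y).
#' @param aligned logical; `TRUE` once a back trial has been gravity-aligned.
#'   Foot trials are never aligned (the foot detector uses the
#'   rotation-invariant resultant).
#' @param unit `"g"` (default) or `"ms2"`; accelerations given in m/s^2 are
#'   divided by 9.80665.
#' @param trial_id,condition free-form metadata labels.
#' @return an object of class `triaxial_trial`.
#' @export
triaxial_trial <- function(samples, fs, site = c("foot", "back"),
                           axis_map = NULL, aligned = FALSE, unit = c("g", "ms2"),
                           trial_id = NA_character_, condition = NA_character_) {
  site <- match.arg(site)
  unit <- match.arg(unit)
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (nrow(samples) < 2L) stop("a trial needs at least 2 samples")
  if (ncol(samples) != 3L) stop("accelerometer samples must have 3 columns")
  if (!all(is.finite(samples))) stop("non-finite acceleration values")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be a positive scalar")
  if (is.null(axis_map)) {
    axis_map <- if (site == "foot") c(ml = 1, ap = 2, vt = 3) else c(ml = 1, ap = 3, vt = 2)
  }
  axis_map <- unlist(axis_map)
  if (!setequal(names(axis_map), c("ml", "ap", "vt")) ||
      !setequal(abs(axis_map), 1:3)) {
    stop("axis_map must be a signed bijection of columns onto {ml, ap, vt}")
  }
  out <- cbind(
    ML = sign(axis_map[["ml"]]) * samples[, abs(axis_map[["ml"]])],
    AP = sign(axis_map[["ap"]]) * samples[, abs(axis_map[["ap"]])],
    VT = sign(axis_map[["vt"]]) * samples[, abs(axis_map[["vt"]])]
  )
  if (unit == "ms2") out <- out / 9.80665
  structure(
    list(site = site, fs = as.numeric(fs), samples = out,
         aligned = isTRUE(aligned), trial_id = trial_id, condition = condition),
    class = "triaxial_trial"
  )
}

#' Construct a vertical ground reaction force trial
#'
#' @param vgrf numeric vector, vertical GRF magnitude in N (non-negative).
#' @param fs sampling rate in Hz.
#' @param trial_id,condition metadata labels.
#' @return an object of class `force_trial`.
#' @export
force_trial <- function(vgrf, fs, trial_id = NA_character_, condition = NA_character_) {
  vgrf <- as.numeric(vgrf)
  if (length(vgrf) < 2L) stop("a trial needs at least 2 samples")
  if (!all(is.finite(vgrf))) stop("non-finite vGRF values")
  if (any(vgrf < 0)) stop("vGRF must be a non-negative magnitude")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be a positive scalar")
  structure(
    list(fs = as.numeric(fs), vgrf = vgrf, trial_id = trial_id, condition = condition),
    class = "force_trial"
  )
}

#' Number of samples and duration of a trial
#' @param trial a `triaxial_trial` or `force_trial`.
#' @return `n_samples()`: integer count; `duration()`: seconds (N / fs).
#' @export
n_samples <- function(trial) {
  if (inherits(trial, "triaxial_trial")) nrow(trial$samples) else length(trial$vgrf)
}

#' @rdname n_samples
#' @export
duration <- function(trial) n_samples(trial) / trial$fs

#' @export
print.triaxial_trial <- function(x, ...) {
  cat(sprintf("<triaxial_trial> site=%s fs=%g Hz n=%d (%.2f s) aligned=%s\n",
              x$site, x$fs, n_samples(x), duration(x), x$aligned))
  invisible(x)
}

#' @export
print.force_trial <- function(x, ...) {
  cat(sprintf("<force_trial> fs=%g Hz n=%d (%.2f s) peak=%.0f N\n",
              x$fs, n_samples(x), duration(x), max(x$vgrf)))
  invisible(x)
}

sample_times <- function(trial) (seq_len(n_samples(trial)) - 1L) / trial$fs

#' Read a trial from CSV
#'
#' Accelerometer CSVs have header `time,ml,ap,vt` (time optional, `fs` is
#' authoritative) with accelerations in g (or m/s^2 with `unit = "ms2"`);
#' force CSVs have header `time,vgrf` (N). Non-numeric body cells raise an
#' error naming the row and column.
#'
#' @param path CSV file path.
#' @param type `"foot"`, `"back"` or `"force"`.
#' @param fs sampling rate in Hz (required; the time column is ignored).
#' @inheritParams triaxial_trial
#' @return a [triaxial_trial()] or [force_trial()].
#' @export
read_trial_csv <- function(path, type = c("foot", "back", "force"), fs,
                           axis_map = NULL, unit = "g",
                           trial_id = NA_character_, condition = NA_character_) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path)
  if (missing(fs) || fs <= 0) stop("fs must be supplied and > 0")
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        strip.white = TRUE)
  names(df) <- tolower(names(df))
  need <- if (type == "force") "vgrf" else c("ml", "ap", "vt")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  num <- lapply(need, function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !(df[[col]] %in% c("NA")))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' at row %d, column '%s'",
                   df[[col]][bad[1]], bad[1], col))
    }
    v
  })
  if (type == "force") {
    force_trial(num[[1]], fs = fs, trial_id = trial_id, condition = condition)
  } else {
    m <- do.call(cbind, num)  # already in ml, ap, vt order
    triaxial_trial(m, fs = fs, site = type,
                   axis_map = c(ml = 1, ap = 2, vt = 3),
                   unit = unit, trial_id = trial_id, condition = condition)
  }
}

#' Write a trial to CSV
#'
#' @param trial a trial object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(trial, path) {
  t <- sample_times(trial)
  df <- if (inherits(trial, "force_trial")) {
    data.frame(time = t, vgrf = trial$vgrf)
  } else {
    data.frame(time = t, ml = trial$samples[, "ML"],
               ap = trial$samples[, "AP"], vt = trial$samples[, "VT"])
  }
  utils::write.csv(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Resample a trial with anti-aliasing
#'
#' Polyphase resampling for rational rate ratios: the series is
#' zero-stuffed, filtered with a centered linear-phase FIR low-pass
#' (odd-reflection edge padding) and decimated, so duration is preserved
#' within one sample period and downsampling is anti-aliased.
#'
#' @param trial a `triaxial_trial` or `force_trial`.
#' @param target_fs new sampling rate in Hz (> 0).
#' @return a trial of the same class at `target_fs`.
#' @export
resample_trial <- function(trial, target_fs) {
  if (!is.numeric(target_fs) || length(target_fs) != 1L || target_fs <= 0) {
    stop("target_fs must be a positive scalar")
  }
  if (abs(target_fs - trial$fs) < 1e-9) return(trial)
  pq <- rational_ratio(target_fs / trial$fs)
  if (inherits(trial, "force_trial")) {
    y <- pmax(0, resample_poly(trial$vgrf, pq[1], pq[2]))
    force_trial(y, fs = target_fs, trial_id = trial$trial_id, condition = trial$condition)
  } else {
    m <- apply(trial$samples, 2, resample_poly, p = pq[1], q = pq[2])
    out <- trial
    out$samples <- m
    colnames(out$samples) <- c("ML", "AP", "VT")
    out$fs <- as.numeric(target_fs)
    out
  }
}

# continued-fraction rational approximation of a rate ratio
rational_ratio <- function(r, max_den = 1000L, tol = 1e-9) {
  p0 <- 0L; q0 <- 1L; p1 <- 1L; q1 <- 0L; x <- r
  repeat {
    a <- floor(x)
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - r) < tol) break
    if (abs(x - a) < 1e-12) break
    x <- 1 / (x - a)
  }
  g <- c(p1, q1)
  if (abs(g[1] / g[2] - r) > 1e-6) {
    stop("sampling-rate ratio has no small rational approximation")
  }
  as.integer(g)
}

# polyphase-equivalent rational resampler: upsample by p, centered FIR
# low-pass at min(Nyquist_in, Nyquist_out), downsample by q.
resample_poly <- function(x, p, q) {
  n <- length(x)
  if (p == q) return(x)
  half <- 10L * max(p, q)              # half-length of the FIR in upsampled samples
  ntaps <- 2L * half + 1L
  h <- signal::fir1(ntaps - 1L, 1 / max(p, q))
  h <- h / sum(h) * p                  # exact unit DC gain (times upsample factor)
  npad <- ceiling(half / p) + 1L       # input-domain padding, odd reflection
  npad <- min(npad, n - 1L)
  left <- 2 * x[1] - x[seq(npad + 1L, 2L)]
  right <- 2 * x[n] - x[seq(n - 1L, n - npad)]
  xp <- c(left, x, right)
  up <- numeric(length(xp) * p)
  up[seq(1L, length(up), by = p)] <- xp
  y <- stats::filter(c(up, numeric(half)), h, method = "convolution", sides = 1)
  y <- as.numeric(y[(half + 1L):(half + length(up))])  # remove group delay
  core <- y[(npad * p + 1L):(npad * p + n * p)]
  n_out <- ceiling(n * p / q)
  core[seq(1L, by = q, length.out = n_out)]
}
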
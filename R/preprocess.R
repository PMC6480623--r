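#' Zero-lag Butterworth low-pass filter
#'
#' Fourth-order Butterworth applied forward and backward (zero phase), the
#' standard biomechanics preprocessing for accelerometer and force signals.
#' Edges are padded by odd (point-symmetric) reflection before filtering to
#' suppress the forward-backward edge transient; DC is preserved exactly for
#' constant input.
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param cutoff cutoff frequency in Hz (default 10, must be < fs/2).
#' @param order filter order (default 4).
#' @return filtered vector, same length as `x`.
#' @export
lowpass <- function(x, fs, cutoff = 10, order = 4) {
  n <- length(x)
  if (cutoff >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  if (n <= 3L * order) stop("series too short to filter (need > 3 x order samples)")
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  # work relative to the first sample (zero filter state matches a zero
  # signal exactly, so DC passes unchanged) and pad by odd reflection long
  # enough for the slowest pole transient to die off
  npad <- min(n - 1L, max(3L * (order + 1L), ceiling(0.5 * fs)))
  x0 <- x[1]
  xc <- x - x0
  left <- -xc[seq(npad + 1L, 2L)]
  right <- 2 * xc[n] - xc[seq(n - 1L, n - npad)]
  xp <- c(left, xc, right)
  y <- signal::filtfilt(bf, xp)
  y[(npad + 1L):(npad + n)] + x0
}

#' Low-pass filter a whole trial
#'
#' Applies [lowpass()] to every acceleration channel, or to the vGRF series
#' (clamped at zero afterwards, since vGRF is a non-negative magnitude and
#' the filter can undershoot at stance edges).
#'
#' @param trial a `triaxial_trial` or `force_trial`.
#' @inheritParams lowpass
#' @return a trial of the same class.
#' @export
lowpass_trial <- function(trial, cutoff = 10, order = 4) {
  if (inherits(trial, "force_trial")) {
    out <- trial
    out$vgrf <- pmax(0, lowpass(trial$vgrf, trial$fs, cutoff, order))
    out
  } else {
    out <- trial
    out$samples <- apply(trial$samples, 2, lowpass, fs = trial$fs,
                         cutoff = cutoff, order = order)
    colnames(out$samples) <- c("ML", "AP", "VT")
    out
  }
}

#' Gravity-align a low-back accelerometer trial
#'
#' Rotates a raw back trial so that the trial-mean acceleration vector (the
#' gravity estimate: over whole strides the motion component averages out)
#' has unit component on the +VT axis, and remaps the raw axes so ML points
#' right, AP anteriorly and VT superiorly. The raw back AP axis points
#' posteriorly; its sign flip together with the raw column reordering is a
#' proper rotation, and the gravity correction is the minimal (axis-angle)
#' rotation taking the mean vector to +VT, so the net transform has
#' determinant +1 and is applied uniformly to all samples. Heading (rotation
#' about VT) is left unchanged; event detection uses only VT and the ML sign.
#'
#' Aligning an already-aligned trial recomputes the gravity rotation only
#' (no second AP flip) and is a no-op up to numerical precision.
#'
#' @param trial a back `triaxial_trial`.
#' @return the aligned trial (`aligned = TRUE`).
#' @export
align_back_to_gravity <- function(trial) {
  stopifnot(inherits(trial, "triaxial_trial"))
  if (trial$site != "back") stop("gravity alignment applies to the back sensor only")
  m <- trial$samples
  if (!trial$aligned) m[, "AP"] <- -m[, "AP"]  # raw back AP is + posterior
  g <- colMeans(m)
  gn <- sqrt(sum(g^2))
  if (gn < 0.5 || gn > 1.5) {
    stop(sprintf(paste("mean acceleration magnitude %.2f g is outside [0.5, 1.5] g;",
                       "sensor does not appear to capture gravity"), gn))
  }
  R <- rotation_to_vt(g / gn)
  out <- trial
  out$samples <- m %*% t(R)
  colnames(out$samples) <- c("ML", "AP", "VT")
  out$aligned <- TRUE
  out
}

# minimal proper rotation taking unit vector u (ML, AP, VT components) to
# the +VT axis e3, via Rodrigues' formula about axis u x e3.
rotation_to_vt <- function(u) {
  e3 <- c(0, 0, 1)
  c_ <- sum(u * e3)
  if (c_ > 1 - 1e-15) return(diag(3))
  if (c_ < -1 + 1e-15) {
    # antipodal: rotate pi about the ML axis
    return(diag(c(1, -1, -1)))
  }
  ax <- c(u[2] * e3[3] - u[3] * e3[2],
          u[3] * e3[1] - u[1] * e3[3],
          u[1] * e3[2] - u[2] * e3[1])
  s <- sqrt(sum(ax^2))
  ax <- ax / s
  K <- matrix(c(0, -ax[3], ax[2],
                ax[3], 0, -ax[1],
                -ax[2], ax[1], 0), 3, 3, byrow = TRUE)
  diag(3) + s * K + (1 - c_) * (K %*% K)
}

#' Trim the ends of a trial
#'
#' Removes a fixed number of seconds (treadmill protocol: steady-state only,
#' e.g. 15 s per end of a 90 s trial) or a fraction of the samples
#' (overground protocol: first and last 5%) from each end. Time restarts at
#' zero at the first retained sample.
#'
#' @param trial a trial object.
#' @param mode `"seconds"` or `"fraction"`.
#' @param amount seconds (mode `"seconds"`) or fraction in `[0, 0.5)`
#'   (mode `"fraction"`) removed from each end.
#' @return the trimmed trial.
#' @export
trim_trial <- function(trial, mode = c("seconds", "fraction"), amount) {
  mode <- match.arg(mode)
  n <- n_samples(trial)
  k <- switch(mode,
    seconds = round(amount * trial$fs),
    fraction = {
      if (amount < 0 || amount >= 0.5) stop("fraction must be in [0, 0.5)")
      floor(amount * n)
    }
  )
  if (k < 0) stop("amount must be non-negative")
  if (2 * k >= n) stop("trimming would consume the whole trial")
  idx <- (k + 1L):(n - k)
  out <- trial
  if (inherits(trial, "force_trial")) out$vgrf <- trial$vgrf[idx]
  else out$samples <- trial$samples[idx, , drop = FALSE]
  out
}

# resultant (Euclidean norm) acceleration, rotation-invariant
resultant <- function(trial) sqrt(rowSums(trial$samples^2))
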
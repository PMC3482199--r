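#' Joint-angle time series container
#'
#' A T x 6 matrix of sagittal joint angles in degrees (columns ankle, knee,
#' hip, LS, C7, AO in proximal-to-distal order) with its sampling rate.
#'
#' @param values T x 6 numeric matrix of angles, degrees.
#' @param fs sampling frequency, Hz.
#' @return object of class `joint_angle_series` with fields `values`, `fs`,
#'   `duration_s`.
#' @export
joint_angle_series <- function(values, fs) {
  values <- as.matrix(values)
  if (ncol(values) != 6L) stop("joint_angle_series: need 6 columns")
  if (any(!is.finite(values))) stop("joint_angle_series: missing/non-finite values")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("joint_angle_series: fs must be a positive scalar (Hz)")
  }
  colnames(values) <- c("ankle", "knee", "hip", "LS", "C7", "AO")
  structure(
    list(values = values, fs = fs, duration_s = nrow(values) / fs),
    class = "joint_angle_series"
  )
}

#' @export
print.joint_angle_series <- function(x, ...) {
  cat(sprintf(
    "joint_angle_series: %d frames x 6 joints, %g Hz (%.1f s), degrees\n",
    nrow(x$values), x$fs, x$duration_s
  ))
  cat("per-joint SD (deg):",
      paste(sprintf("%s=%.3g", colnames(x$values), apply(x$values, 2, stats::sd)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Zero-phase Butterworth low-pass filter
#'
#' Bidirectional (forward-backward, zero-phase) Butterworth low-pass, the
#' standard kinematic smoothing step.  Defaults: order 5, 10 Hz cut-off.
#' The two passes square the one-pass magnitude response, so attenuation in
#' the stop band is doubled in dB and the DC gain stays exactly 1.
#'
#' @param x numeric vector, matrix (filtered column-wise), or
#'   `joint_angle_series`.
#' @param fs sampling rate in Hz (taken from the series if omitted).
#' @param cutoff_hz cut-off frequency, Hz; must satisfy `fs > 2 * cutoff_hz`.
#' @param order filter order of each pass.
#' @return filtered object of the same shape/class as `x`.
#' @export
lowpass <- function(x, fs = NULL, cutoff_hz = 10, order = 5) {
  if (inherits(x, "joint_angle_series")) {
    out <- x
    out$values <- lowpass(x$values, fs = x$fs, cutoff_hz = cutoff_hz,
                          order = order)
    return(out)
  }
  if (is.null(fs)) stop("lowpass: fs required for plain numeric input")
  if (fs <= 2 * cutoff_hz) stop("lowpass: need fs > 2 * cutoff")
  n <- if (is.matrix(x)) nrow(x) else length(x)
  if (n < 3 * (order + 1)) stop("lowpass: series too short for filter warm-up")
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  filt1 <- function(v) {
    mu <- mean(v)  # filter the fluctuation; keeps constants exact
    signal::filtfilt(bf, v - mu) + mu
  }
  if (is.matrix(x)) apply(x, 2, filt1) else filt1(x)
}

#' Average bilateral (left/right) trajectories
#'
#' Elementwise mean of two symmetric marker trajectories.
#'
#' @param left,right equal-length numeric vectors or equal-dim matrices.
#' @return their elementwise mean.
#' @export
average_bilateral <- function(left, right) {
  if (length(left) != length(right)) stop("average_bilateral: length mismatch")
  (left + right) / 2
}

#' Convert joint angles to segment elevation angles (and back)
#'
#' Elevation angle i is the pitch of segment i from vertical: the cumulative
#' sum of joint angles 1..i.  The map is invertible by first differences,
#' so both coordinate systems carry the same information and the UCM/COV
#' analysis can be repeated in either.
#'
#' @param theta a `joint_angle_series` or T x 6 matrix (degrees).
#' @return same type as the input, in elevation (resp. joint) coordinates.
#' @export
joints_to_elevation <- function(theta) {
  if (inherits(theta, "joint_angle_series")) {
    out <- theta
    out$values <- .elevations(theta$values)
    colnames(out$values) <- colnames(theta$values)
    return(out)
  }
  .elevations(theta)
}

#' @rdname joints_to_elevation
#' @param elev elevation-angle series or matrix.
#' @export
elevation_to_joints <- function(elev) {
  diff1 <- function(m) cbind(m[, 1], m[, -1, drop = FALSE] -
                               m[, -ncol(m), drop = FALSE])
  if (inherits(elev, "joint_angle_series")) {
    out <- elev
    out$values <- diff1(elev$values)
    colnames(out$values) <- colnames(elev$values)
    return(out)
  }
  diff1(as.matrix(elev))
}
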
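MARKER_POINTS <- c("toe", "ankle", "knee", "hip", "sacral", "c7", "head",
                   "head_top")

#' Sagittal marker frames container
#'
#' Per-frame sagittal-plane coordinates (x anterior, y vertical, mm) of the
#' chain points.  `head_top` is a nominal massless vertex point above the
#' head point; it carries the atlanto-occipital (AO) angle, which the seven
#' mass-bearing chain points alone cannot encode.
#'
#' @param points named list of T x 2 matrices (columns x, y, mm), one per
#'   point in `c("toe","ankle","knee","hip","sacral","c7","head","head_top")`.
#' @param fs sampling frequency, Hz.
#' @return object of class `marker_frames`.
#' @export
marker_frames <- function(points, fs) {
  if (!all(MARKER_POINTS %in% names(points))) {
    stop("marker_frames: missing chain points: ",
         paste(setdiff(MARKER_POINTS, names(points)), collapse = ", "))
  }
  points <- lapply(points[MARKER_POINTS], function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 2L) stop("marker_frames: each point needs x,y columns")
    if (any(!is.finite(p))) stop("marker_frames: non-finite coordinates")
    colnames(p) <- c("x", "y")
    p
  })
  n <- vapply(points, nrow, integer(1))
  if (length(unique(n)) != 1L) stop("marker_frames: inconsistent frame counts")
  if (fs <= 0) stop("marker_frames: fs must be positive")
  structure(list(points = points, fs = fs, n_frames = n[[1]]),
            class = "marker_frames")
}

#' @export
print.marker_frames <- function(x, ...) {
  cat(sprintf("marker_frames: %d frames, %g Hz, points: %s\n",
              x$n_frames, x$fs, paste(names(x$points), collapse = ", ")))
  invisible(x)
}

#' Synthesize sagittal markers from joint angles by forward kinematics
#'
#' Places the chain points for every frame of a joint-angle series, with the
#' ankle fixed at (0, ankle height), the toe anterior of it at ground level,
#' and a massless `head_top` vertex segment rotated by the AO angle above
#' the head point.  Optional i.i.d. Gaussian measurement noise emulates
#' marker-tracking error.
#'
#' @param theta a `joint_angle_series`.
#' @param chain a `chain_model`.
#' @param noise_sd_mm SD of additive Gaussian noise per coordinate per
#'   frame, mm (0 = noise-free).
#' @param seed optional integer seed for the noise.
#' @return a `marker_frames` object.
#' @export
synthesize_markers <- function(theta, chain, noise_sd_mm = 0, seed = NULL) {
  stopifnot(inherits(theta, "joint_angle_series"), inherits(chain, "chain_model"))
  v <- theta$values
  pts <- .chain_points(chain, v)
  n <- nrow(v)
  ank <- c(0, chain$ankle_height_mm)
  e6 <- .elevations(v)[, 6] * DEG2RAD
  mk <- list(
    toe = cbind(rep(chain$toe_offset_mm, n), rep(0, n)),
    ankle = cbind(rep(ank[1], n), rep(ank[2], n)),
    knee = cbind(pts$x[, 1] + ank[1], pts$y[, 1] + ank[2]),
    hip = cbind(pts$x[, 2] + ank[1], pts$y[, 2] + ank[2]),
    sacral = cbind(pts$x[, 3] + ank[1], pts$y[, 3] + ank[2]),
    c7 = cbind(pts$x[, 4] + ank[1], pts$y[, 4] + ank[2]),
    head = cbind(pts$x[, 5] + ank[1], pts$y[, 5] + ank[2])
  )
  mk$head_top <- cbind(mk$head[, 1] + chain$head_top_mm * sin(e6),
                       mk$head[, 2] + chain$head_top_mm * cos(e6))
  out <- marker_frames(mk, fs = theta$fs)
  if (noise_sd_mm > 0) out <- add_marker_noise(out, sd_mm = noise_sd_mm,
                                               seed = seed)
  out
}

#' Add Gaussian measurement noise to marker frames
#'
#' Adds i.i.d. zero-mean Gaussian noise independently to every coordinate of
#' every point in every frame, emulating optoelectronic tracking error
#' (spatial accuracy of the order of 2 mm).
#'
#' @param frames a `marker_frames` object.
#' @param sd_mm noise SD in mm (>= 0).
#' @param seed optional integer seed; the same seed reproduces the output.
#' @return a `marker_frames` object.
#' @export
add_marker_noise <- function(frames, sd_mm = 2, seed = NULL) {
  stopifnot(inherits(frames, "marker_frames"))
  if (!is.numeric(sd_mm) || sd_mm < 0) stop("add_marker_noise: sd must be >= 0")
  if (sd_mm == 0) return(frames)
  if (!is.null(seed)) set.seed(seed)
  frames$points <- lapply(frames$points, function(p) {
    p + matrix(stats::rnorm(length(p), 0, sd_mm), nrow(p), 2)
  })
  frames
}

#' Compute joint angles from sagittal marker frames
#'
#' The ankle angle is the pitch of the shank (ankle-to-knee segment) from
#' vertical; each subsequent angle is the relative planar angle between
#' consecutive segments along the chain, with the AO angle taken between
#' the C7-to-head segment and the head-to-head_top vertex segment.
#' Angles are positive for anterior pitch, in degrees.
#'
#' @param frames a `marker_frames` object.
#' @return a `joint_angle_series`.
#' @export
markers_to_angles <- function(frames) {
  stopifnot(inherits(frames, "marker_frames"))
  if (frames$n_frames < 2L) stop("markers_to_angles: need at least 2 frames")
  p <- frames$points
  segs <- list(
    c("ankle", "knee"), c("knee", "hip"), c("hip", "sacral"),
    c("sacral", "c7"), c("c7", "head"), c("head", "head_top")
  )
  pitch <- sapply(segs, function(s) {
    d <- p[[s[2]]] - p[[s[1]]]
    if (any(rowSums(d^2) == 0)) {
      stop("markers_to_angles: degenerate (zero-length) segment ",
           s[1], "->", s[2])
    }
    atan2(d[, 1], d[, 2]) / DEG2RAD
  })
  theta <- cbind(pitch[, 1], pitch[, -1, drop = FALSE] -
                   pitch[, -ncol(pitch), drop = FALSE])
  joint_angle_series(theta, fs = frames$fs)
}
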
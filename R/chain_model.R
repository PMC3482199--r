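#' Planar six-joint sagittal chain model
#'
#' Builds the kinematic model used throughout the package: a planar chain of
#' six sagittal joints (ankle, knee, hip, lumbo-sacral LS, lower neck C7,
#' atlanto-occipital AO) connecting five massive segments (shank, thigh,
#' pelvis, trunk, head).  The head segment's mass is lumped at the "head
#' point", the distal end of the C7-to-head segment; the AO joint rotates
#' massless geometry distal to that point, so AO affects head *orientation*
#' but neither head *position* nor the whole-body centre of mass.
#'
#' Default anthropometry approximates a ~1.75 m adult using standard relative
#' segmental masses and centre-of-mass positions, with foot mass folded into
#' the shank and arm mass (arms hanging at the sides) into the trunk.
#'
#' Conventions: angles are in degrees, positive = anterior (forward) pitch;
#' x is positive anterior, y positive vertical; lengths in mm.
#'
#' @param segment_lengths named or ordered numeric(5): distances in mm
#'   ankle->knee, knee->hip, hip->sacral, sacral->C7, C7->head point.
#' @param mass_fractions numeric(5): relative segment masses (shank, thigh,
#'   pelvis, trunk, head); normalized to sum to 1.
#' @param com_fractions numeric(5): proximal-to-distal CoM position fraction
#'   of each segment, each in \[0, 1\].  The head default is 1 (mass lumped
#'   at the head point).
#' @param toe_offset_mm,ankle_height_mm,head_top_mm fixed geometry for the
#'   toe point (anterior of, and below, the ankle) and the massless vertex
#'   segment above the head point used to carry the AO angle in marker data.
#' @return an object of class `chain_model`.
#' @examples
#' ch <- build_chain()
#' forward_tasks(ch, rep(0, 6))
#' @export
build_chain <- function(segment_lengths = c(
                          shank = 440, thigh = 440, pelvis = 100,
                          trunk = 450, head = 150
                        ),
                        mass_fractions = c(
                          shank = 0.122, thigh = 0.200, pelvis = 0.142,
                          trunk = 0.455, head = 0.081
                        ),
                        com_fractions = c(
                          shank = 0.433, thigh = 0.433, pelvis = 0.5,
                          trunk = 0.5, head = 1.0
                        ),
                        toe_offset_mm = 150,
                        ankle_height_mm = 80,
                        head_top_mm = 120) {
  segment_lengths <- as.numeric(segment_lengths)
  mass_fractions <- as.numeric(mass_fractions)
  com_fractions <- as.numeric(com_fractions)
  if (length(segment_lengths) != 5L || any(!is.finite(segment_lengths)) ||
      any(segment_lengths <= 0)) {
    stop("invalid anthropometry: need 5 finite positive segment lengths (mm)")
  }
  if (length(mass_fractions) != 5L || any(mass_fractions < 0) ||
      sum(mass_fractions) <= 0) {
    stop("invalid anthropometry: mass fractions must be >= 0 with positive sum")
  }
  if (length(com_fractions) != 5L || any(com_fractions < 0 | com_fractions > 1)) {
    stop("invalid anthropometry: CoM fractions must lie in [0, 1]")
  }
  if (head_top_mm <= 0 || toe_offset_mm <= 0) {
    stop("invalid anthropometry: auxiliary geometry must be positive")
  }
  structure(list(
    joint_names = c("ankle", "knee", "hip", "LS", "C7", "AO"),
    segment_names = c("shank", "thigh", "pelvis", "trunk", "head"),
    segment_lengths = segment_lengths,
    mass_fractions = mass_fractions / sum(mass_fractions),
    com_fractions = com_fractions,
    toe_offset_mm = toe_offset_mm,
    ankle_height_mm = ankle_height_mm,
    head_top_mm = head_top_mm
  ), class = "chain_model")
}

#' @export
print.chain_model <- function(x, ...) {
  cat("Planar sagittal chain: 6 joints (", paste(x$joint_names, collapse = ", "),
      ")\n", sep = "")
  tab <- data.frame(
    segment = x$segment_names,
    length_mm = x$segment_lengths,
    mass_fraction = x$mass_fractions,
    com_fraction = x$com_fractions
  )
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Names of the four postural task variables
#'
#' @return character(4): `com_position` and `head_position` (anterior-
#'   posterior positions, mm), `trunk_orientation` and `head_orientation`
#'   (pitch, degrees).
#' @export
ucm_tasks <- function() {
  c("com_position", "head_position", "trunk_orientation", "head_orientation")
}

DEG2RAD <- pi / 180

## Elevation angles (segment pitch from vertical) for each row of a T x 6
## angle matrix: cumulative sums along the chain.
.cumsum_mat <- function(n) {
  U <- matrix(0, n, n)
  U[upper.tri(U, diag = TRUE)] <- 1
  U
}

.elevations <- function(theta) {
  theta <- .as_angle_matrix(theta)
  theta %*% .cumsum_mat(6)
}

.as_angle_matrix <- function(theta) {
  if (inherits(theta, "joint_angle_series")) theta <- theta$values
  if (is.null(dim(theta))) theta <- matrix(theta, nrow = 1)
  theta <- as.matrix(theta)
  if (ncol(theta) != 6L) stop("expected 6 joint-angle columns")
  if (any(!is.finite(theta))) stop("angles must be finite")
  theta
}

## Chain point x/y above the ankle for each frame; returns list of T x 5
## matrices (columns knee, hip, sacral, C7, head).
.chain_points <- function(chain, theta) {
  e <- .elevations(theta)[, 1:5, drop = FALSE] * DEG2RAD
  L <- chain$segment_lengths
  U <- .cumsum_mat(5)
  list(
    x = sweep(sin(e), 2, L, `*`) %*% U,
    y = sweep(cos(e), 2, L, `*`) %*% U
  )
}

## Anterior-posterior and vertical CoM relative to the ankle, vectorized
## over frames.  Head segment CoM sits at com_fractions[5] along C7->head
## (default 1: lumped at the head point).
.chain_com <- function(chain, theta) {
  e <- .elevations(theta)[, 1:5, drop = FALSE] * DEG2RAD
  L <- chain$segment_lengths
  m <- chain$mass_fractions
  cf <- chain$com_fractions
  U <- .cumsum_mat(5)
  sx <- sweep(sin(e), 2, L, `*`)
  sy <- sweep(cos(e), 2, L, `*`)
  cx <- cbind(0, (sx %*% U)[, 1:4, drop = FALSE])
  cy <- cbind(0, (sy %*% U)[, 1:4, drop = FALSE])
  segx <- cx + sweep(sx, 2, cf, `*`)
  segy <- cy + sweep(sy, 2, cf, `*`)
  list(x = as.numeric(segx %*% m), y = as.numeric(segy %*% m))
}

#' Anterior-posterior and vertical whole-body CoM of the chain
#'
#' Position of the model centre of mass relative to the ankle joint, in mm.
#' Mostly a building block for `forward_tasks()`, exported for checking the
#' segmental-mass model directly.
#'
#' @param chain a `chain_model`.
#' @param theta 6 joint angles (degrees) or a T x 6 matrix / series.
#' @return list with numeric vectors `x` (anterior) and `y` (vertical), mm.
#' @export
chain_com <- function(chain, theta) .chain_com(chain, theta)

#' Evaluate the four task variables for joint configurations
#'
#' Maps joint angles to the four task variables through the planar forward
#' model: anterior-posterior CoM position and head-point position (mm,
#' relative to the ankle), trunk orientation (pitch of the sacral-to-C7
#' segment, i.e. the sum of the first four joint angles, degrees) and head
#' orientation (sum of all six joint angles, degrees).
#'
#' @param chain a `chain_model`.
#' @param theta 6 angles (degrees) or a T x 6 matrix / `joint_angle_series`.
#' @return data.frame with T rows and columns `com_position`,
#'   `head_position`, `trunk_orientation`, `head_orientation`.
#' @export
forward_tasks <- function(chain, theta) {
  theta <- .as_angle_matrix(theta)
  e <- .elevations(theta)
  pts <- .chain_points(chain, theta)
  data.frame(
    com_position = .chain_com(chain, theta)$x,
    head_position = pts$x[, 5],
    trunk_orientation = e[, 4],
    head_orientation = e[, 6]
  )
}

#' Task sensitivities (Jacobian) of a task variable
#'
#' Analytic gradient of one task variable with respect to the six joint
#' angles, evaluated at a reference posture.  Positional tasks are reported
#' in mm per degree (so the factor pi/180 is included); orientation tasks
#' are dimensionless and posture-independent: trunk orientation is
#' (1, 1, 1, 1, 0, 0) and head orientation (1, 1, 1, 1, 1, 1) at any
#' posture.  Entries distal to the task point are exactly zero; in
#' particular the AO entry of both positional tasks is 0 because the AO
#' joint only rotates massless geometry distal to the head point.
#'
#' @param chain a `chain_model`.
#' @param theta_ref reference posture, 6 angles in degrees.
#' @param task one of [ucm_tasks()].
#' @return named numeric(6) of sensitivities.
#' @export
task_jacobian <- function(chain, theta_ref, task) {
  task <- match.arg(task, ucm_tasks())
  theta_ref <- as.numeric(.as_angle_matrix(theta_ref)[1, ])
  J <- switch(task,
    trunk_orientation = c(1, 1, 1, 1, 0, 0),
    head_orientation = c(1, 1, 1, 1, 1, 1),
    head_position = {
      e <- cumsum(theta_ref)[1:5] * DEG2RAD
      Lcos <- chain$segment_lengths * cos(e)
      c(rev(cumsum(rev(Lcos))), 0) * DEG2RAD
    },
    com_position = {
      e <- cumsum(theta_ref)[1:5] * DEG2RAD
      L <- chain$segment_lengths
      m <- chain$mass_fractions
      cf <- chain$com_fractions
      J <- numeric(6)
      for (j in 1:5) {
        acc <- 0
        for (k in j:5) {
          inner <- if (k > j) sum(L[j:(k - 1)] * cos(e[j:(k - 1)])) else 0
          acc <- acc + m[k] * (inner + cf[k] * L[k] * cos(e[k]))
        }
        J[j] <- acc * DEG2RAD
      }
      J
    }
  )
  names(J) <- c("ankle", "knee", "hip", "LS", "C7", "AO")
  J
}

#' Task model: forward map plus Jacobian at a reference posture
#'
#' Bundles one task variable's scalar forward map and its 6-vector of
#' sensitivities, linearized at `theta_ref` (by default the posture itself;
#' in pipeline use, the per-trial mean posture).
#'
#' @inheritParams task_jacobian
#' @return list with elements `name`, `forward` (function: angles ->
#'   scalar/vector of task values) and `jacobian` (numeric(6)).
#' @export
task_model <- function(chain, theta_ref, task) {
  task <- match.arg(task, ucm_tasks())
  force(chain)
  list(
    name = task,
    forward = function(theta) forward_tasks(chain, theta)[[task]],
    jacobian = task_jacobian(chain, theta_ref, task)
  )
}

#' Task sensitivities in segment elevation-angle coordinates
#'
#' The same task variable expressed as a function of segment elevation
#' angles e (cumulative joint angles) instead of joint angles.  Since
#' theta = D e with D the first-difference matrix, the elevation-space
#' gradient is J_theta %*% D.
#'
#' @inheritParams task_jacobian
#' @return numeric(6) of sensitivities with respect to elevation angles.
#' @export
elevation_jacobian <- function(chain, theta_ref, task) {
  J <- task_jacobian(chain, theta_ref, task)
  D <- diag(6)
  D[cbind(2:6, 1:5)] <- -1
  as.numeric(J %*% D)
}
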
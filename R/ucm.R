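#' Orthonormal task-equivalent / task-relevant subspace bases
#'
#' Splits joint space into the null space of a task Jacobian (the
#' uncontrolled manifold, dimension d-1 for a scalar task on d joints) and
#' its 1-dimensional orthogonal complement (the range direction, parallel
#' to the Jacobian).  The null basis comes from the SVD of J and is made
#' deterministic by a fixed sign convention: the first entry of each basis
#' vector exceeding 1e-12 in magnitude is positive.
#'
#' @param J numeric Jacobian vector (any dimension >= 2), not all zero.
#' @return list with `null_basis` (d x (d-1), orthonormal columns),
#'   `range_basis` (d x 1 unit vector, proportional to J) and `J`.
#' @export
subspace_basis <- function(J) {
  J <- as.numeric(J)
  d <- length(J)
  if (d < 2L) stop("subspace_basis: need at least 2 joints")
  if (all(J == 0) || any(!is.finite(J))) {
    stop("subspace_basis: Jacobian must be finite and nonzero")
  }
  sv <- svd(matrix(J, nrow = 1), nu = 0, nv = d)
  N <- sv$v[, 2:d, drop = FALSE]
  r <- J / sqrt(sum(J^2))
  fix_sign <- function(v) {
    i <- which(abs(v) > 1e-12)[1]
    if (v[i] < 0) -v else v
  }
  N <- matrix(apply(N, 2, fix_sign), nrow = d)
  list(null_basis = N, range_basis = matrix(r, ncol = 1), J = J)
}

.popvar <- function(x) mean(x^2) - mean(x)^2

#' UCM decomposition of joint-angle fluctuations
#'
#' Demeans the angle series about a reference posture and projects the
#' deviations onto the task-equivalent (null-space) and task-relevant
#' (range-space) subspaces of the task Jacobian.  Variability in each
#' subspace is normalized to its dimensionality: TEV is the mean population
#' variance (divisor T) across the d-1 null-basis coordinates, TRV the
#' population variance of the single range coordinate.  The UCM index is
#' TEV/TRV; values reliably above 1 indicate motor-equivalent stabilization
#' of the task variable.
#'
#' @param theta a `joint_angle_series` or T x d numeric matrix (degrees).
#' @param J task Jacobian (numeric(d)), e.g. from [task_jacobian()].
#' @param reference `"mean"` (default: per-trial mean posture) or a
#'   numeric(d) reference configuration.
#' @return object of class `ucm_decomposition`: coordinate series
#'   (`tev_coords` T x (d-1), `trv_coords` T x 1), joint-space components
#'   (`tev_joint`, `trv_joint`, both T x d, summing to the demeaned input),
#'   per-DOF variances `tev_var`, `trv_var` (deg^2), `ucm_index`,
#'   `log_index`, and `undefined` (TRUE when TRV = 0 makes the index
#'   undefined; no error is thrown).
#' @export
ucm_decompose <- function(theta, J, reference = "mean") {
  v <- if (inherits(theta, "joint_angle_series")) theta$values else as.matrix(theta)
  if (any(!is.finite(v))) stop("ucm_decompose: non-finite angles")
  if (nrow(v) < 2L) stop("ucm_decompose: need at least 2 samples")
  J <- as.numeric(J)
  if (ncol(v) != length(J)) stop("ucm_decompose: Jacobian/series dimension mismatch")
  ref <- if (identical(reference, "mean")) colMeans(v) else as.numeric(reference)
  if (length(ref) != ncol(v)) stop("ucm_decompose: bad reference posture")
  dev <- sweep(v, 2, ref)
  B <- subspace_basis(J)
  a <- dev %*% B$null_basis
  b <- dev %*% B$range_basis
  tev_var <- mean(apply(a, 2, .popvar))
  trv_var <- .popvar(b[, 1])
  undefined <- trv_var == 0
  ucm_index <- if (undefined) NA_real_ else tev_var / trv_var
  structure(list(
    tev_coords = a, trv_coords = b,
    tev_joint = tcrossprod(a, B$null_basis),
    trv_joint = tcrossprod(b, B$range_basis),
    tev_var = tev_var, trv_var = trv_var,
    ucm_index = ucm_index,
    log_index = if (undefined) NA_real_ else log(ucm_index),
    undefined = undefined,
    basis = B, reference = ref,
    n = nrow(v)
  ), class = "ucm_decomposition")
}

#' @export
print.ucm_decomposition <- function(x, ...) {
  cat(sprintf(
    "UCM decomposition: T=%d, %d null dims\n  TEV=%.4g deg^2/DOF, TRV=%.4g deg^2/DOF",
    x$n, ncol(x$tev_coords), x$tev_var, x$trv_var
  ))
  if (x$undefined) {
    cat("  [index undefined: TRV = 0]\n")
  } else {
    cat(sprintf(", UCM index=%.3g (log %.3g)\n", x$ucm_index, x$log_index))
  }
  invisible(x)
}

#' Group summary of log-transformed UCM (or COV) indices
#'
#' Log-transforms one index per trial/subject and summarizes across the
#' group: mean log index, SEM, and a one-sample t test of the mean log
#' index against 0 (index against 1).  Undefined or non-positive indices
#' are excluded with a warning and counted.
#'
#' @param indices numeric vector of UCM/COV indices (one per subject/trial),
#'   or a list of `ucm_decomposition` objects.
#' @return list: `n_used`, `n_excluded`, `mean_log`, `sem_log`, `t`, `df`,
#'   `p`.
#' @export
ucm_index_stats <- function(indices) {
  if (is.list(indices) && all(vapply(indices, inherits, logical(1),
                                     "ucm_decomposition"))) {
    indices <- vapply(indices, function(d) {
      if (d$undefined) NA_real_ else d$ucm_index
    }, numeric(1))
  }
  test <- suppressWarnings(one_sample_log_test(indices))
  if (test$n_excluded > 0) {
    warning(sprintf("ucm_index_stats: %d undefined/non-positive indices excluded",
                    test$n_excluded))
  }
  test
}
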
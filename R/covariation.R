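#' Decorrelated surrogate of a joint-angle series
#'
#' Destroys cross-joint covariation by independently permuting each joint's
#' column over time (optionally in contiguous blocks, which preserves most
#' of the within-joint autocorrelation).  Marginal distributions of every
#' joint are preserved exactly.
#'
#' @param theta a `joint_angle_series` or T x d matrix.
#' @param block_s optional block length in seconds for block permutation
#'   (`NULL`, the default, permutes single samples).  Requires a
#'   `joint_angle_series` (to know fs).
#' @return object of the same type with each column permuted.
#' @export
make_surrogate <- function(theta, block_s = NULL) {
  is_series <- inherits(theta, "joint_angle_series")
  v <- if (is_series) theta$values else as.matrix(theta)
  if (nrow(v) < 2L) stop("make_surrogate: need at least 2 samples")
  perm <- .column_permutations(nrow(v), ncol(v),
                               block = .block_samples(block_s, theta))
  out <- vapply(seq_len(ncol(v)), function(j) v[perm[, j], j],
                numeric(nrow(v)))
  colnames(out) <- colnames(v)
  if (is_series) joint_angle_series(out, theta$fs) else out
}

.block_samples <- function(block_s, theta) {
  if (is.null(block_s)) return(1L)
  if (!inherits(theta, "joint_angle_series")) {
    stop("make_surrogate: block_s needs a joint_angle_series (fs unknown)")
  }
  max(1L, as.integer(round(block_s * theta$fs)))
}

## One independent permutation per column, sample-wise or in blocks.
.column_permutations <- function(n, d, block = 1L) {
  one <- function() {
    if (block <= 1L) return(sample.int(n))
    starts <- seq.int(1L, n, by = block)
    idx <- unlist(lapply(sample(seq_along(starts)), function(b) {
      seq.int(starts[b], min(starts[b] + block - 1L, n))
    }))
    idx[seq_len(n)]
  }
  vapply(seq_len(d), function(j) one(), integer(n))
}

#' Covariation-by-randomization (COV) index
#'
#' Assesses motor-equivalent coordination at the task level: the task
#' variable is computed through the full nonlinear forward model for the
#' original series and for surrogate series whose cross-joint covariation
#' has been destroyed by independent column permutations of the angle
#' deviations about the trial mean.  The COV index is the ratio of the mean
#' surrogate task variance to the original task variance; values reliably
#' above 1 indicate that cross-joint covariation reduces task variability.
#'
#' @param theta a `joint_angle_series`.
#' @param chain a `chain_model`.
#' @param task one of [ucm_tasks()].
#' @param n_surrogates number of surrogates (>= 1), default 100.
#' @param seed integer seed; the same seed and input reproduce the result.
#' @param coords `"joint"` (default) to permute joint-angle deviations or
#'   `"elevation"` to permute segment elevation-angle deviations.
#' @param permute `"deviations"` (default) permutes demeaned deviations and
#'   re-adds the mean posture; `"raw"` permutes the raw angle columns.
#' @param block_s optional permutation block length in seconds.
#' @return object of class `cov_result`: `original_task_var`,
#'   `surrogate_task_vars`, `cov_index`, `log_index`, `n_surrogates`,
#'   `seed`, `undefined`.
#' @export
cov_index <- function(theta, chain, task, n_surrogates = 100, seed = NULL,
                      coords = c("joint", "elevation"),
                      permute = c("deviations", "raw"), block_s = NULL) {
  stopifnot(inherits(theta, "joint_angle_series"), inherits(chain, "chain_model"))
  coords <- match.arg(coords)
  permute <- match.arg(permute)
  task <- match.arg(task, ucm_tasks())
  if (n_surrogates < 1L) stop("cov_index: n_surrogates must be >= 1")
  if (!is.null(seed)) set.seed(seed)

  v <- theta$values
  task_var <- function(angles) .popvar(forward_tasks(chain, angles)[[task]])
  original <- task_var(v)

  work <- if (coords == "elevation") .elevations(v) else v
  mu <- colMeans(work)
  dev <- sweep(work, 2, mu)
  base <- if (permute == "deviations") dev else work
  block <- .block_samples(block_s, theta)

  surr <- vapply(seq_len(n_surrogates), function(s) {
    perm <- .column_permutations(nrow(base), ncol(base), block = block)
    w <- vapply(seq_len(ncol(base)), function(j) base[perm[, j], j],
                numeric(nrow(base)))
    if (permute == "deviations") w <- sweep(w, 2, mu, `+`)
    if (coords == "elevation") w <- elevation_to_joints(w)
    task_var(w)
  }, numeric(1))

  undefined <- original == 0
  idx <- if (undefined) NA_real_ else mean(surr) / original
  structure(list(
    task = task, original_task_var = original, surrogate_task_vars = surr,
    cov_index = idx,
    log_index = if (undefined) NA_real_ else log(idx),
    n_surrogates = n_surrogates, seed = seed, coords = coords,
    undefined = undefined
  ), class = "cov_result")
}

#' @export
print.cov_result <- function(x, ...) {
  cat(sprintf("COV (%s, %s coords): original var=%.4g, mean surrogate var=%.4g",
              x$task, x$coords, x$original_task_var,
              mean(x$surrogate_task_vars)))
  if (x$undefined) cat("  [index undefined: original variance 0]\n")
  else cat(sprintf(", COV index=%.3g (log %.3g), %d surrogates\n",
                   x$cov_index, x$log_index, x$n_surrogates))
  invisible(x)
}
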
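UCM_LAGS_S <- c(1, 2, 4, 8, 16, 32, 64, 128)

#' Time-lagged squared autocorrelation (coefficient of determination)
#'
#' Squared Pearson correlation between a series and its copy shifted by
#' `lag_samples`: `R^2 = cor(x[1..T-L], x[L+1..T])^2`.  R^2 lies in \[0,1\]
#' and, unlike variance-based measures, is invariant to affine rescaling of
#' the series, so persistence comparisons between components are
#' independent of their amplitudes.
#'
#' @param x numeric vector.
#' @param lag_samples positive integer lag in samples.
#' @param min_overlap minimum number of overlapping samples required.
#' @return R^2 in \[0, 1\]; `NA` (flagged, no error) if either segment has
#'   zero variance.
#' @export
lagged_r2 <- function(x, lag_samples, min_overlap = 30) {
  x <- as.numeric(x)
  n <- length(x)
  lag_samples <- as.integer(lag_samples)
  if (lag_samples < 1L) stop("lagged_r2: lag must be >= 1 sample")
  if (n - lag_samples < min_overlap) {
    stop(sprintf("lagged_r2: overlap %d below minimum %d",
                 n - lag_samples, min_overlap))
  }
  a <- x[seq_len(n - lag_samples)]
  b <- x[seq.int(lag_samples + 1L, n)]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)^2
}

#' Persistence transform for coefficients of determination
#'
#' Inverse hyperbolic tangent with the definition interval rescaled from
#' \[-1, 1\] to \[0, 1\]: `z = atanh(2 r2 - 1)`.  Used to normalize R^2
#' values before t tests.  r2 is clipped to `[eps, 1 - eps]` so z is always
#' finite; the transform is monotone and invertible inside the clip range.
#'
#' @param r2 numeric vector of R^2 values in \[0, 1\].
#' @param eps clipping margin.
#' @return transformed values z.
#' @export
r2_transform <- function(r2, eps = 1e-6) {
  if (any(r2 < 0 | r2 > 1, na.rm = TRUE)) stop("r2_transform: r2 outside [0,1]")
  atanh(2 * pmin(pmax(r2, eps), 1 - eps) - 1)
}

.lag_samples <- function(lags_s, fs) {
  L <- as.integer(round(lags_s * fs))
  if (any(diff(lags_s) <= 0)) stop("lags must be strictly increasing")
  L
}

#' Persistence profile of each column of a series
#'
#' Lagged squared autocorrelation of every column (joint angles or task
#' variables) at the given lags.  Lags in seconds are converted to samples
#' by `round(lag_s * fs)`.
#'
#' @param x a `joint_angle_series`, or numeric matrix/data.frame/vector.
#' @param fs sampling rate, Hz (taken from the series if omitted).
#' @param lags_s lags in seconds (default the dyadic set 1..128 s).
#' @param min_overlap minimum overlap passed to [lagged_r2()].
#' @return data.frame in long format: `series`, `lag_s`, `r2`, `z`.
#' @export
series_persistence <- function(x, fs = NULL, lags_s = UCM_LAGS_S,
                               min_overlap = 30) {
  if (inherits(x, "joint_angle_series")) {
    fs <- x$fs
    x <- x$values
  }
  if (is.null(fs)) stop("series_persistence: fs required")
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("s", seq_len(ncol(x)))
  L <- .lag_samples(lags_s, fs)
  out <- expand.grid(series = colnames(x), lag_s = lags_s,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$r2 <- mapply(function(s, li) lagged_r2(x[, s], L[match(li, lags_s)],
                                             min_overlap = min_overlap),
                   out$series, out$lag_s)
  out$z <- r2_transform(out$r2)
  out
}

#' Persistence of TEV and TRV components of a UCM decomposition
#'
#' Computes the lagged squared autocorrelation of the task-equivalent and
#' task-relevant components.  TEV is multidimensional, so its R^2 at each
#' lag is an average over dimensions, in one of two schemes:
#' \describe{
#'   \item{equal}{R^2 per null-basis coordinate (d-1 series), unweighted
#'     mean.  Depends on the (deterministic, SVD-derived) choice of null
#'     basis; see [tev_basis_diagnostic()].}
#'   \item{sensitivity}{R^2 per *joint* of the parallel (task-equivalent)
#'     component in joint coordinates, averaged with weights
#'     `w_j = J_j^2 / sum(J_k^2)`, so joints with little influence on the
#'     task variable contribute little.  Zero-sensitivity joints get weight
#'     0 and are excluded.}
#' }
#' TRV is univariate (the single range coordinate) in both schemes.
#'
#' @param dec a `ucm_decomposition`.
#' @param fs sampling rate of the decomposed series, Hz.
#' @param lags_s lags in seconds.
#' @param weighting `"equal"`, `"sensitivity"`, or both.
#' @param min_overlap minimum overlap passed to [lagged_r2()].
#' @return data.frame: `component` (TEV/TRV), `weighting`, `lag_s`, `r2`,
#'   `z`.
#' @export
component_persistence <- function(dec, fs, lags_s = UCM_LAGS_S,
                                  weighting = c("equal", "sensitivity"),
                                  min_overlap = 30) {
  stopifnot(inherits(dec, "ucm_decomposition"))
  weighting <- match.arg(weighting, several.ok = TRUE)
  L <- .lag_samples(lags_s, fs)
  J <- dec$basis$J

  col_r2 <- function(m, li) {
    apply(m, 2, lagged_r2, lag_samples = L[li], min_overlap = min_overlap)
  }
  rows <- list()
  for (w in weighting) {
    tev <- vapply(seq_along(lags_s), function(li) {
      if (w == "equal") {
        mean(col_r2(dec$tev_coords, li))
      } else {
        wt <- J^2 / sum(J^2)
        keep <- wt > 0
        r2 <- col_r2(dec$tev_joint[, keep, drop = FALSE], li)
        sum(wt[keep] * r2) / sum(wt[keep])
      }
    }, numeric(1))
    trv <- vapply(seq_along(lags_s), function(li) {
      lagged_r2(dec$trv_coords[, 1], L[li], min_overlap = min_overlap)
    }, numeric(1))
    rows[[w]] <- data.frame(
      component = rep(c("TEV", "TRV"), each = length(lags_s)),
      weighting = w,
      lag_s = rep(lags_s, 2),
      r2 = c(tev, trv)
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$z <- r2_transform(out$r2)
  out
}

#' Basis-sensitivity diagnostic for equal-weight TEV persistence
#'
#' The equal-weight TEV persistence averages R^2 over null-basis
#' coordinates, and the null basis of a Jacobian is only defined up to
#' rotation.  The package's SVD-derived basis is deterministic, but on
#' anisotropic data a different orthonormal re-spanning can change the
#' average.  This diagnostic recomputes the equal-weight TEV profile in a
#' randomly rotated null basis and reports both, surfacing any basis
#' dependence rather than hiding it.
#'
#' @param dec a `ucm_decomposition`.
#' @param fs sampling rate, Hz.
#' @param lags_s lags in seconds.
#' @param seed seed for the random rotation.
#' @return data.frame: `lag_s`, `r2_fixed`, `r2_rotated`, `abs_diff`.
#' @export
tev_basis_diagnostic <- function(dec, fs, lags_s = UCM_LAGS_S, seed = 1L) {
  stopifnot(inherits(dec, "ucm_decomposition"))
  L <- .lag_samples(lags_s, fs)
  k <- ncol(dec$tev_coords)
  set.seed(seed)
  Q <- qr.Q(qr(matrix(stats::rnorm(k * k), k, k)))
  rot <- dec$tev_coords %*% Q
  prof <- function(m) {
    vapply(L, function(l) mean(apply(m, 2, lagged_r2, lag_samples = l)),
           numeric(1))
  }
  r2f <- prof(dec$tev_coords)
  r2r <- prof(rot)
  data.frame(lag_s = lags_s, r2_fixed = r2f, r2_rotated = r2r,
             abs_diff = abs(r2f - r2r))
}
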
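#' Holm (step-down Bonferroni) correction
#'
#' Wraps the standard step-down Holm procedure: sorted p-values p(i) are
#' compared to alpha/(m - i + 1); adjusted p-values are the running maxima
#' of (m - i + 1) * p(i), capped at 1 (as in `stats::p.adjust`).  Decisions
#' are monotone: rejecting a p-value implies rejecting all smaller ones.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @param alpha family-wise significance level.
#' @return data.frame with `p`, `p_adj`, `reject` in the input order.
#' @export
holm_correct <- function(pvals, alpha = 0.05) {
  pvals <- as.numeric(pvals)
  if (any(!is.na(pvals) & (pvals < 0 | pvals > 1))) {
    stop("holm_correct: p-values must lie in [0, 1]")
  }
  adj <- stats::p.adjust(pvals, method = "holm")
  data.frame(p = pvals, p_adj = adj, reject = !is.na(adj) & adj <= alpha)
}

#' One-sample t test of log-transformed indices against 0
#'
#' UCM and COV indices are positive ratios; testing whether they reliably
#' exceed 1 is done on the natural-log scale against 0.  Non-positive or
#' missing indices cannot be log-transformed and are excluded (counted in
#' `n_excluded`).
#'
#' @param values positive numeric indices (one per subject/trial).
#' @return list: `n_used`, `n_excluded`, `mean_log`, `sem_log`, `t`, `df`,
#'   `p` (two-sided).
#' @export
one_sample_log_test <- function(values) {
  values <- as.numeric(values)
  bad <- is.na(values) | values <= 0
  if (any(bad)) {
    warning(sprintf("one_sample_log_test: excluding %d non-positive/undefined values",
                    sum(bad)))
  }
  lv <- log(values[!bad])
  if (length(lv) < 2L) stop("one_sample_log_test: need >= 2 usable values")
  if (stats::sd(lv) == 0) {
    # degenerate sample: all logs identical; t = 0 when the common value is
    # already the null value, otherwise undefined (flagged NA)
    on_null <- mean(lv) == 0
    return(list(
      n_used = length(lv), n_excluded = sum(bad),
      mean_log = mean(lv), sem_log = 0,
      t = if (on_null) 0 else NA_real_, df = length(lv) - 1,
      p = if (on_null) 1 else NA_real_
    ))
  }
  tt <- stats::t.test(lv, mu = 0)
  list(
    n_used = length(lv), n_excluded = sum(bad),
    mean_log = mean(lv), sem_log = stats::sd(lv) / sqrt(length(lv)),
    t = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value
  )
}

#' Paired TEV-vs-TRV comparison per time lag with Holm correction
#'
#' Paired two-sided t tests of transformed persistence (z values) between
#' the task-equivalent and task-relevant components at each lag, with the
#' Holm correction applied across lags.  Lags where every subject's paired
#' difference is exactly zero have an undefined t statistic and are flagged
#' (`NA` p, not rejected).
#'
#' @param tev_z,trv_z numeric matrices, subjects x lags, of transformed
#'   persistence values for the two components.
#' @param lags_s lags in seconds labelling the columns.
#' @param alpha family-wise level for the Holm decisions.
#' @return data.frame: `lag_s`, `mean_diff` (TEV - TRV), `t`, `df`, `p`,
#'   `p_adj`, `reject`.
#' @export
paired_component_test <- function(tev_z, trv_z, lags_s = UCM_LAGS_S,
                                  alpha = 0.05) {
  tev_z <- as.matrix(tev_z)
  trv_z <- as.matrix(trv_z)
  if (!all(dim(tev_z) == dim(trv_z))) {
    stop("paired_component_test: dimension mismatch between components")
  }
  if (ncol(tev_z) != length(lags_s)) {
    stop("paired_component_test: one column per lag required")
  }
  res <- lapply(seq_along(lags_s), function(li) {
    d <- tev_z[, li] - trv_z[, li]
    if (all(d == 0) || stats::sd(d) == 0) {
      return(data.frame(lag_s = lags_s[li], mean_diff = mean(d),
                        t = NA_real_, df = length(d) - 1, p = NA_real_))
    }
    tt <- stats::t.test(tev_z[, li], trv_z[, li], paired = TRUE)
    data.frame(lag_s = lags_s[li], mean_diff = mean(d),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  })
  out <- do.call(rbind, res)
  hc <- holm_correct(out$p, alpha = alpha)
  out$p_adj <- hc$p_adj
  out$reject <- hc$reject
  out
}
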
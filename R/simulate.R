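#' Configuration for the minimal-intervention sway simulator
#'
#' The simulator emulates quiet-standing joint-angle fluctuations under a
#' minimal-intervention control scheme: deviations orthogonal to a task
#' variable's uncontrolled manifold are corrected quickly (short time
#' constant `tau_orth`), while deviations within the manifold are left to
#' accumulate (long `tau_par`).  Each of the five null-space dimensions and
#' the one range dimension follows an independent stationary AR(1) process
#' with coefficient `phi = exp(-1 / (tau * fs))` and the configured
#' stationary SD.
#'
#' Defaults are the shipped study conditions: 100 Hz, 300 s recordings,
#' `tau_par = 30` s vs `tau_orth = 0.5` s, `sd_par = 1.0` deg vs
#' `sd_orth = 0.3` deg per dimension, structuring the CoM-position task.
#' These amplitudes put the per-joint angle SDs in the 0.1-2 deg range
#' typical of quiet standing.
#'
#' @param task task variable whose UCM structures the dynamics.
#' @param fs sampling frequency, Hz.
#' @param duration_s trial duration, seconds.
#' @param tau_par,tau_orth correction time constants (s) parallel /
#'   orthogonal to the UCM; both > 0.
#' @param sd_par,sd_orth stationary SDs (deg) per dimension; >= 0.
#' @param mean_posture 6 mean joint angles, degrees.
#' @param chain a `chain_model` (defines the task Jacobian at
#'   `mean_posture`).
#' @param marker_noise_sd_mm Gaussian marker noise used when synthesizing
#'   markers from the simulated angles (0 = none).
#' @param seed optional integer seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(task = "com_position", fs = 100, duration_s = 300,
                       tau_par = 30, tau_orth = 0.5,
                       sd_par = 1.0, sd_orth = 0.3,
                       mean_posture = rep(0, 6),
                       chain = build_chain(),
                       marker_noise_sd_mm = 0, seed = NULL) {
  task <- match.arg(task, ucm_tasks())
  if (tau_par <= 0 || tau_orth <= 0) stop("sim_config: tau must be > 0")
  if (sd_par < 0 || sd_orth < 0) stop("sim_config: sd must be >= 0")
  if (fs <= 0 || duration_s <= 0) stop("sim_config: fs and duration must be > 0")
  if (length(mean_posture) != 6L || any(!is.finite(mean_posture))) {
    stop("sim_config: mean_posture must be 6 finite angles")
  }
  if (marker_noise_sd_mm < 0) stop("sim_config: marker noise sd must be >= 0")
  structure(list(
    task = task, fs = fs, duration_s = duration_s,
    tau_par = tau_par, tau_orth = tau_orth,
    sd_par = sd_par, sd_orth = sd_orth,
    mean_posture = as.numeric(mean_posture), chain = chain,
    marker_noise_sd_mm = marker_noise_sd_mm, seed = seed
  ), class = "sim_config")
}

## Stationary AR(1) sample of length n: coefficient phi, stationary sd.
.ar1 <- function(n, phi, sd) {
  if (sd == 0) return(numeric(n))
  innov <- stats::rnorm(n, 0, sd * sqrt(1 - phi^2))
  innov[1] <- stats::rnorm(1, 0, sd)
  as.numeric(stats::filter(innov, phi, method = "recursive"))
}

#' Simulate minimal-intervention postural sway
#'
#' Generates a joint-angle series as `theta(t) = mean_posture + N a(t) +
#' r b(t)`, where N and r are the package's deterministic null/range bases
#' of the task Jacobian at the mean posture, the five columns of `a` are
#' independent AR(1) processes with time constant `tau_par` and stationary
#' SD `sd_par`, and `b` is one AR(1) with `tau_orth`, `sd_orth`.
#'
#' @param cfg a `sim_config`.
#' @param rotate_basis if TRUE, generate in a randomly rotated null basis
#'   instead of the analysis basis (robustness option; the distribution of
#'   the data is unchanged only when the five parallel dimensions share one
#'   SD, as in the default).
#' @return a `joint_angle_series` with attribute `"sim_config"`.
#' @export
simulate_sway <- function(cfg, rotate_basis = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- as.integer(round(cfg$fs * cfg$duration_s))
  J <- task_jacobian(cfg$chain, cfg$mean_posture, cfg$task)
  B <- subspace_basis(J)
  N <- B$null_basis
  if (rotate_basis) {
    k <- ncol(N)
    Q <- qr.Q(qr(matrix(stats::rnorm(k * k), k, k)))
    N <- N %*% Q
  }
  phi_par <- exp(-1 / (cfg$tau_par * cfg$fs))
  phi_orth <- exp(-1 / (cfg$tau_orth * cfg$fs))
  a <- vapply(seq_len(ncol(N)), function(i) .ar1(n, phi_par, cfg$sd_par),
              numeric(n))
  b <- .ar1(n, phi_orth, cfg$sd_orth)
  theta <- matrix(cfg$mean_posture, n, 6, byrow = TRUE) +
    tcrossprod(a, N) + tcrossprod(b, B$range_basis)
  out <- joint_angle_series(theta, cfg$fs)
  attr(out, "sim_config") <- cfg
  out
}

#' Simulate a cohort of independent subjects
#'
#' Independent realizations of [simulate_sway()] with per-subject seeds
#' derived from a base seed (`seed + subject index`).  Optional
#' anthropometry jitter rescales each subject's segment lengths by
#' independent Gaussian factors, emulating between-subject differences in
#' body geometry (and hence in positional Jacobians).
#'
#' @param n_subjects number of subjects (default 14).
#' @param cfg a `sim_config` template.
#' @param seed base integer seed.
#' @param anthropometry_jitter SD of the multiplicative length jitter
#'   (e.g. 0.05 for 5%); 0 disables it.
#' @return list of `joint_angle_series`, one per subject.
#' @export
simulate_cohort <- function(n_subjects = 14, cfg = sim_config(), seed = 1L,
                            anthropometry_jitter = 0) {
  stopifnot(inherits(cfg, "sim_config"), n_subjects >= 1)
  lapply(seq_len(n_subjects), function(i) {
    cfg_i <- cfg
    cfg_i$seed <- as.integer(seed + i)
    if (anthropometry_jitter > 0) {
      set.seed(cfg_i$seed + 1000000L)
      fac <- pmax(0.5, 1 + stats::rnorm(5, 0, anthropometry_jitter))
      ch <- cfg$chain
      cfg_i$chain <- build_chain(
        segment_lengths = ch$segment_lengths * fac,
        mass_fractions = ch$mass_fractions,
        com_fractions = ch$com_fractions,
        toe_offset_mm = ch$toe_offset_mm,
        ankle_height_mm = ch$ankle_height_mm,
        head_top_mm = ch$head_top_mm
      )
    }
    simulate_sway(cfg_i)
  })
}
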
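test_chain <- function(...) build_chain(...)

## Small random posture within a physiological-looking range (degrees).
random_posture <- function() stats::rnorm(6, 0, 5)

## Central finite-difference gradient of a task's forward model; the
## independent oracle for the analytic Jacobians (mm/deg or d.u.).
fd_jacobian <- function(chain, theta, task, h = 1e-4) {
  vapply(1:6, function(j) {
    e <- rep(0, 6)
    e[j] <- h
    (forward_tasks(chain, theta + e)[[task]] -
       forward_tasks(chain, theta - e)[[task]]) / (2 * h)
  }, numeric(1))
}

## i.i.d. isotropic Gaussian angle series.
isotropic_series <- function(n, sd = 1, fs = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  joint_angle_series(matrix(stats::rnorm(n * 6, 0, sd), n, 6), fs = fs)
}

## Stationary AR(1) with coefficient phi and stationary sd.
ar1_series <- function(n, phi, sd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  innov <- stats::rnorm(n, 0, sd * sqrt(1 - phi^2))
  innov[1] <- stats::rnorm(1, 0, sd)
  as.numeric(stats::filter(innov, phi, method = "recursive"))
}

## The shipped study conditions (see sim_config defaults), overridable.
paperlike_config <- function(...) {
  args <- list(task = "com_position", fs = 100, duration_s = 300,
               tau_par = 30, tau_orth = 0.5, sd_par = 1.0, sd_orth = 0.3)
  over <- list(...)
  do.call(sim_config, utils::modifyList(args, over))
}
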
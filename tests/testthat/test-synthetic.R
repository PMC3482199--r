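test_that("config validation catches bad parameters", {
  expect_error(sim_config(tau_par = 0), "tau")
  expect_error(sim_config(sd_orth = -1), "sd")
  expect_error(sim_config(mean_posture = rep(0, 5)), "mean_posture")
  expect_s3_class(paperlike_config(), "sim_config")
})

test_that("simulated dimensions have the configured stationary SDs", {
  # fast mixing (short tau) so 300 s pins the stationary SD to ~1-2%
  cfg <- paperlike_config(seed = 51, tau_par = 0.1, tau_orth = 0.1)
  s <- simulate_sway(cfg)
  expect_equal(nrow(s$values), 30000)
  J <- task_jacobian(cfg$chain, cfg$mean_posture, cfg$task)
  B <- subspace_basis(J)
  dev <- sweep(s$values, 2, cfg$mean_posture)
  a_sd <- apply(dev %*% B$null_basis, 2, sd)
  b_sd <- sd(dev %*% B$range_basis)
  expect_equal(unname(a_sd), rep(1.0, 5), tolerance = 0.03)
  expect_equal(b_sd, 0.3, tolerance = 0.03)
  # per-joint angle SDs in the physiological 0.1-2 deg range
  sds <- apply(s$values, 2, sd)
  expect_true(all(sds > 0.1 & sds < 2))
})

test_that("symmetric dynamics give a null log UCM index", {
  cfg <- sim_config(tau_par = 0.05, tau_orth = 0.05, sd_par = 1, sd_orth = 1,
                    seed = 52)
  s <- simulate_sway(cfg)
  J <- task_jacobian(cfg$chain, colMeans(s$values), cfg$task)
  expect_lt(abs(ucm_decompose(s, J)$log_index), 0.05)
})

test_that("paper-like dynamics separate TEV and TRV in amount and persistence", {
  cfg <- paperlike_config(seed = 53)
  s <- simulate_sway(cfg)
  J <- task_jacobian(cfg$chain, colMeans(s$values), cfg$task)
  d <- ucm_decompose(s, J)
  expect_gt(d$log_index, 0)
  cp <- component_persistence(d, fs = cfg$fs, lags_s = c(2, 4, 8, 16, 32),
                              weighting = "equal")
  tev <- cp$r2[cp$component == "TEV"]
  trv <- cp$r2[cp$component == "TRV"]
  expect_true(all(tev > trv))
  # TEV persistence tracks the generating AR(1) closed form phi^(2L) at
  # lags where the 300 s trial estimates it reliably
  phi <- exp(-1 / (cfg$tau_par * cfg$fs))
  for (L in c(2, 4)) {
    expect_lt(abs(cp$r2[cp$component == "TEV" & cp$lag_s == L] -
                    phi^(2 * L * cfg$fs)), 0.12)
  }
})

test_that("amplitude and persistence are controlled by separate knobs", {
  base <- paperlike_config(seed = 54, duration_s = 120)
  amp <- paperlike_config(seed = 54, duration_s = 120, sd_par = 2.0)
  slow <- paperlike_config(seed = 54, duration_s = 120, tau_par = 1)
  index_and_profile <- function(cfg) {
    s <- simulate_sway(cfg)
    J <- task_jacobian(cfg$chain, colMeans(s$values), cfg$task)
    d <- ucm_decompose(s, J)
    cp <- component_persistence(d, fs = cfg$fs, lags_s = c(1, 2),
                                weighting = "equal")
    list(log_index = d$log_index, tev_r2 = cp$r2[cp$component == "TEV"])
  }
  b <- index_and_profile(base)
  a <- index_and_profile(amp)
  sl <- index_and_profile(slow)
  # doubling sd_par adds ~log(4) to the index but leaves persistence alone
  expect_equal(a$log_index - b$log_index, log(4), tolerance = 0.25)
  expect_equal(a$tev_r2, b$tev_r2, tolerance = 0.05)
  # shortening tau_par drops persistence markedly
  expect_lt(sl$tev_r2[1], b$tev_r2[1] - 0.3)
})

test_that("cohorts are reproducible, subject-distinct, and power the group test", {
  cfg <- paperlike_config(duration_s = 60)
  co <- simulate_cohort(4, cfg, seed = 55)
  co2 <- simulate_cohort(4, cfg, seed = 55)
  expect_identical(co, co2)
  expect_false(identical(co[[1]]$values, co[[2]]$values))
  expect_true(all(vapply(co, function(s) nrow(s$values) == 6000, logical(1))))

  # group one-sample test on log UCM indices rejects under the
  # minimal-intervention configuration
  ch <- cfg$chain
  idx <- vapply(co, function(s) {
    ucm_decompose(s, task_jacobian(ch, colMeans(s$values), cfg$task))$ucm_index
  }, numeric(1))
  st <- one_sample_log_test(idx)
  expect_gt(st$mean_log, 0)
  expect_lt(st$p, 0.05)
})

test_that("anthropometry jitter varies subject chains without breaking them", {
  co <- simulate_cohort(3, paperlike_config(duration_s = 10), seed = 56,
                        anthropometry_jitter = 0.05)
  cfgs <- lapply(co, attr, "sim_config")
  l1 <- cfgs[[1]]$chain$segment_lengths
  l2 <- cfgs[[2]]$chain$segment_lengths
  expect_false(isTRUE(all.equal(l1, l2)))
  expect_equal(sum(cfgs[[1]]$chain$mass_fractions), 1, tolerance = 1e-12)
})

test_that("rotated-basis generation leaves the analysis invariants intact", {
  cfg <- paperlike_config(seed = 57, duration_s = 60)
  s <- simulate_sway(cfg, rotate_basis = TRUE)
  J <- task_jacobian(cfg$chain, colMeans(s$values), cfg$task)
  d <- ucm_decompose(s, J)
  popvar <- function(x) mean(x^2) - mean(x)^2
  expect_equal(5 * d$tev_var + d$trv_var,
               sum(apply(s$values, 2, popvar)), tolerance = 1e-9)
  expect_gt(d$log_index, 0)
})
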
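test_that("lagged R^2 has the right limits on periodic, white and AR(1) input", {
  fs <- 100
  t <- (0:9999) / fs
  x <- sin(2 * pi * 1 * t)
  expect_equal(lagged_r2(x, lag_samples = fs), 1, tolerance = 1e-9)

  set.seed(41)
  w <- rnorm(1e5)
  for (L in c(1, 10, 500)) expect_lt(lagged_r2(w, L), 0.001)

  # AR(1), phi = 0.9: autocorrelation at lag L is phi^L, so R^2 = phi^(2L).
  # 0.03 is ~4 sd of the sampling error of r^2 at the worst lag (Bartlett
  # variance of r at T = 1e5)
  x <- ar1_series(1e5, 0.9, seed = 42)
  for (L in c(1, 2, 4, 8, 16, 32, 64, 128)) {
    expect_lt(abs(lagged_r2(x, L) - 0.9^(2 * L)), 0.03,
              label = sprintf("R2 error at lag %d", L))
  }
  expect_equal(lagged_r2(x, 1), 0.81, tolerance = 0.02)
})

test_that("lagged R^2 rejects infeasible lags and flags zero variance", {
  x <- rnorm(100)
  expect_error(lagged_r2(x, 100), "overlap")
  expect_error(lagged_r2(x, 80, min_overlap = 30), "overlap")
  expect_error(lagged_r2(x, 0), "lag must be")
  expect_true(is.na(lagged_r2(rep(1, 100), 10)))
})

test_that("R^2 is invariant to affine rescaling of the series", {
  set.seed(43)
  x <- ar1_series(5000, 0.95)
  for (i in 1:5) {
    a <- runif(1, 0.1, 10)
    b <- rnorm(1, 0, 50)
    expect_equal(lagged_r2(a * x + b, 25), lagged_r2(x, 25),
                 tolerance = 1e-12)
  }
})

test_that("the persistence transform is the rescaled inverse hyperbolic tangent", {
  expect_equal(r2_transform(0.5), 0)
  r2 <- seq(0.01, 0.99, by = 0.01)
  z <- r2_transform(r2)
  expect_true(all(diff(z) > 0))
  expect_equal((tanh(z) + 1) / 2, r2, tolerance = 1e-9)
  # clipping keeps the endpoints finite
  expect_true(all(is.finite(r2_transform(c(0, 1)))))
  expect_error(r2_transform(1.2), "outside")
})

test_that("column-wise persistence matches brute-force recomputation", {
  set.seed(44)
  s <- joint_angle_series(
    vapply(1:6, function(j) ar1_series(6000, 0.98), numeric(6000)), fs = 100
  )
  prof <- series_persistence(s, lags_s = c(1, 2, 4))
  expect_equal(nrow(prof), 18)
  # direct recomputation of one cell
  expect_equal(prof$r2[prof$series == "hip" & prof$lag_s == 2],
               cor(s$values[1:5800, 3], s$values[201:6000, 3])^2,
               tolerance = 1e-12)
  # a task series (sum of AR(1) joints) matches brute force too
  task <- forward_tasks(build_chain(), s)$trunk_orientation
  tp <- series_persistence(task, fs = 100, lags_s = c(1, 4))
  expect_equal(tp$r2[tp$lag_s == 4],
               cor(task[1:5600], task[401:6000])^2, tolerance = 1e-12)
})

test_that("a 300 s trial at 100 Hz supports the full dyadic lag set", {
  set.seed(45)
  s <- joint_angle_series(matrix(rnorm(30000 * 6), ncol = 6), fs = 100)
  prof <- series_persistence(s)
  expect_equal(sort(unique(prof$lag_s)), c(1, 2, 4, 8, 16, 32, 64, 128))
  expect_true(all(is.finite(prof$r2)))
})

test_that("TEV averaging schemes behave as specified", {
  # all five null dimensions carry the *same* series -> equal-weight TEV
  # R^2 equals the single-dimension R^2
  J <- c(1, 1, 1, 1, 0, 0)
  B <- subspace_basis(J)
  a <- ar1_series(4000, 0.97, seed = 46)
  v <- tcrossprod(matrix(a, ncol = 1)[, rep(1, 5)], B$null_basis) +
    tcrossprod(rnorm(4000, 0, 0.1), B$range_basis)
  d <- ucm_decompose(v, J)
  cp <- component_persistence(d, fs = 100, lags_s = c(1, 2), weighting = "equal")
  expect_equal(cp$r2[cp$component == "TEV" & cp$lag_s == 1],
               lagged_r2(d$tev_coords[, 1], 100), tolerance = 1e-6)

  # sensitivity weighting with J = (1,1,1,1,0,0): C7/AO get weight zero.
  # plant a strongly persistent signal only in those two joints; the
  # weighted TEV persistence must ignore it
  set.seed(47)
  n <- 4000
  slow <- ar1_series(n, 0.999, sd = 3)
  v2 <- cbind(matrix(rnorm(4 * n, 0, 1), n, 4), slow, slow * 0.8)
  d2 <- ucm_decompose(v2, J)
  cp2 <- component_persistence(d2, fs = 100, lags_s = c(2),
                               weighting = c("equal", "sensitivity"))
  tev_eq <- cp2$r2[cp2$component == "TEV" & cp2$weighting == "equal"]
  tev_wt <- cp2$r2[cp2$component == "TEV" & cp2$weighting == "sensitivity"]
  expect_gt(tev_eq, tev_wt + 0.2)
})

test_that("persistence is independent of component amplitude", {
  set.seed(48)
  v <- matrix(rnorm(3000 * 6), 3000, 6)
  J <- rnorm(6)
  d1 <- ucm_decompose(v, J)
  d2 <- ucm_decompose(v * 5, J)
  p1 <- component_persistence(d1, fs = 100, lags_s = c(1, 2, 4))
  p2 <- component_persistence(d2, fs = 100, lags_s = c(1, 2, 4))
  expect_equal(p1$r2, p2$r2, tolerance = 1e-9)
})

test_that("basis-rotation diagnostic agrees on isotropic data, flags anisotropy", {
  set.seed(49)
  J <- c(1, 1, 1, 1, 0, 0)
  iso <- matrix(rnorm(20000 * 6), 20000, 6)
  d_iso <- ucm_decompose(iso, J)
  diag_iso <- tev_basis_diagnostic(d_iso, fs = 100, lags_s = c(1, 2), seed = 1)
  expect_lt(max(diag_iso$abs_diff), 0.02)

  # anisotropic null-space content: one slow dimension among four fast ones
  B <- subspace_basis(J)
  a <- cbind(ar1_series(20000, 0.999, sd = 2),
             matrix(rnorm(20000 * 4), ncol = 4))
  d_ani <- ucm_decompose(tcrossprod(a, B$null_basis) +
                           tcrossprod(rnorm(20000, 0, 0.1), B$range_basis), J)
  diag_ani <- tev_basis_diagnostic(d_ani, fs = 100, lags_s = c(1, 2), seed = 1)
  expect_true(is.data.frame(diag_ani) && all(c("r2_fixed", "r2_rotated")
                                             %in% names(diag_ani)))
})
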
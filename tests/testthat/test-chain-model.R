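test_that("chain construction normalizes masses and validates anthropometry", {
  ch <- build_chain()
  expect_length(ch$joint_names, 6L)
  expect_equal(sum(ch$mass_fractions), 1, tolerance = 1e-12)
  expect_length(ucm_tasks(), 4L)

  ch2 <- build_chain(mass_fractions = c(1, 2, 3, 4, 5))
  expect_equal(sum(ch2$mass_fractions), 1, tolerance = 1e-12)
  expect_equal(ch2$mass_fractions, (1:5) / 15)

  expect_error(build_chain(segment_lengths = c(-1, 1, 1, 1, 1)),
               "invalid anthropometry")
  expect_error(build_chain(segment_lengths = c(0, 1, 1, 1, 1)),
               "invalid anthropometry")
  expect_error(build_chain(com_fractions = c(0.5, 0.5, 0.5, 0.5, 1.2)),
               "invalid anthropometry")
})

test_that("chain CoM matches hand-computed two-segment configurations", {
  L <- 400
  # only the first two segments carry mass, CoM at segment midpoints:
  # point masses at heights L/2 and 3L/2 -> chain CoM height = L
  ch_mid <- build_chain(segment_lengths = c(L, L, 1, 1, 1),
                        mass_fractions = c(0.5, 0.5, 0, 0, 0),
                        com_fractions = c(0.5, 0.5, 1, 1, 1))
  com <- chain_com(ch_mid, rep(0, 6))
  expect_equal(com$y, L, tolerance = 1e-9)
  expect_equal(com$x, 0, tolerance = 1e-12)

  # same masses at the distal ends -> heights L and 2L -> CoM height 1.5 L
  ch_dist <- build_chain(segment_lengths = c(L, L, 1, 1, 1),
                         mass_fractions = c(0.5, 0.5, 0, 0, 0),
                         com_fractions = c(1, 1, 1, 1, 1))
  expect_equal(chain_com(ch_dist, rep(0, 6))$y, 1.5 * L, tolerance = 1e-9)
})

test_that("forward models obey the reference-posture and small-chain cases", {
  ch <- build_chain()
  f0 <- forward_tasks(ch, rep(0, 6))
  expect_equal(f0$trunk_orientation, 0)
  expect_equal(f0$head_orientation, 0)
  expect_equal(f0$com_position, 0, tolerance = 1e-12)
  expect_equal(f0$head_position, 0, tolerance = 1e-12)

  f1 <- forward_tasks(ch, c(1, 1, 1, 1, 0, 0))
  expect_equal(f1$trunk_orientation, 4)
  expect_equal(f1$head_orientation, 4)

  # rigid rotation at the ankle displaces the head point by
  # (total chain length) * sin(angle)
  f2 <- forward_tasks(ch, c(10, 0, 0, 0, 0, 0))
  expect_equal(f2$head_position, sum(ch$segment_lengths) * sin(10 * pi / 180),
               tolerance = 1e-9)

  expect_error(forward_tasks(ch, c(1, 2, 3, NA, 5, 6)), "finite")
})

test_that("analytic Jacobians have the structural zero/one pattern", {
  ch <- build_chain()
  th <- random_posture()
  expect_equal(unname(task_jacobian(ch, th, "trunk_orientation")),
               c(1, 1, 1, 1, 0, 0))
  expect_equal(unname(task_jacobian(ch, th, "head_orientation")),
               c(1, 1, 1, 1, 1, 1))
  expect_identical(unname(task_jacobian(ch, th, "com_position")[6]), 0)
  expect_identical(unname(task_jacobian(ch, th, "head_position")[6]), 0)
  expect_error(task_jacobian(ch, th, "hand_position"))
})

test_that("analytic Jacobians match finite differences at 20 random postures", {
  ch <- build_chain()
  set.seed(42)
  for (i in 1:20) {
    th <- random_posture()
    for (task in ucm_tasks()) {
      a <- unname(task_jacobian(ch, th, task))
      f <- fd_jacobian(ch, th, task)
      expect_lt(max(abs(a - f) / pmax(abs(f), 1)), 1e-6,
                label = sprintf("rel err, %s posture %d", task, i))
    }
  }
})

test_that("orientation Jacobians are posture-independent, positional ones vary", {
  ch <- build_chain()
  set.seed(7)
  th1 <- random_posture()
  th2 <- random_posture()
  expect_identical(task_jacobian(ch, th1, "trunk_orientation"),
                   task_jacobian(ch, th2, "trunk_orientation"))
  expect_identical(task_jacobian(ch, th1, "head_orientation"),
                   task_jacobian(ch, th2, "head_orientation"))
  expect_false(isTRUE(all.equal(task_jacobian(ch, th1, "com_position"),
                                task_jacobian(ch, th2, "com_position"))))
})

test_that("task_model bundles a forward map consistent with its Jacobian", {
  ch <- build_chain()
  tm <- task_model(ch, rep(0, 6), "head_position")
  expect_equal(tm$name, "head_position")
  expect_equal(tm$forward(c(10, 0, 0, 0, 0, 0)),
               sum(ch$segment_lengths) * sin(10 * pi / 180), tolerance = 1e-9)
  expect_equal(tm$jacobian, task_jacobian(ch, rep(0, 6), "head_position"))
})

test_that("elevation-space Jacobian equals the chain-rule transform", {
  ch <- build_chain()
  # trunk orientation is itself the 4th elevation angle
  expect_equal(unname(elevation_jacobian(ch, rep(0, 6), "trunk_orientation")),
               c(0, 0, 0, 1, 0, 0))
  # finite differences in elevation space as oracle
  th <- c(2, -1, 1, -2, 3, 1)
  e0 <- as.numeric(joints_to_elevation(matrix(th, 1)))
  for (task in c("com_position", "head_position")) {
    Je <- elevation_jacobian(ch, th, task)
    fd <- vapply(1:6, function(j) {
      h <- 1e-4
      ep <- e0; ep[j] <- ep[j] + h
      em <- e0; em[j] <- em[j] - h
      (forward_tasks(ch, elevation_to_joints(matrix(ep, 1)))[[task]] -
         forward_tasks(ch, elevation_to_joints(matrix(em, 1)))[[task]]) / (2 * h)
    }, numeric(1))
    expect_equal(Je, fd, tolerance = 1e-6)
  }
})
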
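test_that("the exactly solvable linear limit is reproduced", {
  # a = b = d = k = 0 linearizes the system:
  #   y(t) = c + (y0 - c) e^(-t)
  #   x(t) = x0 + c t + (y0 - c)(1 - e^(-t)) + A1 (1 - cos(2 pi f1 t)) / (2 pi f1)
  p <- hr_params(a = 0, b = 0, c = 1, d = 0, k = 0)
  d <- hr_drive(A1 = 2, f1 = 0.5)
  ic <- c(x = 0.3, y = -1, phi = 0)
  traj <- hr_integrate(p, d, ic, t_span = c(0, 20))
  t <- traj$t
  y_exact <- 1 + (-1 - 1) * exp(-t)
  x_exact <- 0.3 + t + (-2) * (1 - exp(-t)) +
    2 * (1 - cos(2 * pi * 0.5 * t)) / (2 * pi * 0.5)
  expect_lt(max(abs(traj$states[, 1] - x_exact)), 1e-6)
  expect_lt(max(abs(traj$states[, 2] - y_exact)), 1e-6)
})

test_that("the unforced system settles onto its stable equilibrium", {
  # unforced k = 0 equilibria solve x^3 + 2 x^2 - 1 = 0; the branch at
  # x = -(1 + sqrt(5))/2 is attracting
  xs <- -(1 + sqrt(5)) / 2
  p <- hr_params(k = 0)
  traj <- hr_integrate(p, hr_drive(A1 = 0), c(xs - 0.3, 1 - 5 * xs^2, 0),
                       t_span = c(0, 400))
  n <- length(traj$t)
  s_end <- traj$states[n, ]
  s_mid <- traj$states[traj$t == 200, ]
  expect_lt(sqrt(sum((s_end - s_mid)^2)), 1e-4)
  expect_equal(s_end[1], xs, tolerance = 1e-5)
})

test_that("integration is deterministic and bounded on the chaotic preset", {
  p <- hr_params(k = 1)
  d <- hr_drive(A1 = 3, f1 = 0.5)
  t1 <- hr_integrate(p, d, c(-5, 0, 0), t_span = c(0, 300))
  t2 <- hr_integrate(p, d, c(-5, 0, 0), t_span = c(0, 300))
  expect_identical(t1$states, t2$states)
  expect_lt(max(abs(t1$states[, 1])), 10)
  expect_true(all(diff(t1$t) > 0))
  expect_false(any(!is.finite(t1$states)))
})

test_that("tolerance halving barely moves the periodic orbit", {
  p <- hr_params(k = 1)
  d <- hr_drive(A1 = 5.5, f1 = 0.5)
  a <- hr_integrate(p, d, c(5, 0, 0), t_span = c(0, 100))
  b <- hr_integrate(p, d, c(5, 0, 0), t_span = c(0, 100),
                    rtol = 5e-9, atol = 5e-11)
  expect_lt(abs(a$states[length(a$t), 1] - b$states[length(b$t), 1]), 1e-3)
})

test_that("transient discarding keeps the suffix and records the cut", {
  p <- hr_params(k = 1)
  d <- hr_drive(A1 = 5.5, f1 = 0.5)
  traj <- hr_integrate(p, d, c(5, 0, 0), t_span = c(0, 50))
  expect_identical(discard_transient(traj, 0)$states, traj$states)
  half <- discard_transient(traj, 25)
  expect_equal(length(half$t), (length(traj$t) + 1) %/% 2, tolerance = 1)
  expect_true(all(half$t >= 25))
  expect_identical(half$meta$t_cut, 25)
  expect_error(discard_transient(traj, 60), "outside")
})

test_that("divergent dynamics raise an integration failure", {
  # b < 0 gives a cubic blow-up from a large initial condition
  p <- hr_params(b = -1, k = 0)
  expect_error(hr_integrate(p, hr_drive(A1 = 0), c(5, 0, 0),
                            t_span = c(0, 50)),
               "integration failure")
})

test_that("trajectories can be built from external series", {
  t <- seq(0, 10, by = 0.1)
  traj <- as_hr_trajectory(t, cbind(sin(t), cos(t), 0))
  expect_s3_class(traj, "hr_trajectory")
  expect_equal(traj$meta$sample_dt, 0.1)
  expect_error(as_hr_trajectory(c(1, 1, 2), cbind(1:3, 0, 0)))
})
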
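test_that("memductance is the quadratic flux function", {
  p <- hr_params()
  expect_identical(memductance(0, p), 0)
  expect_equal(memductance(1, p), 0.01)
  expect_equal(memductance(-5, p), 0.25)   # even in phi
  expect_equal(memductance(c(-2, 2), p), c(0.04, 0.04))
  expect_equal(memductance(3, hr_params(alpha = 0.5)), 0.5 + 0.09)
})

test_that("drive current superimposes the two sinusoids", {
  d <- hr_drive(A1 = 1, f1 = 0.05, A2 = 1, f2 = 0.05)
  expect_equal(drive_current(5, d), 2)
  expect_equal(drive_current(15, d), -2)
  d1 <- hr_drive(A1 = 2.3, f1 = 0.4, A2 = 0, f2 = 17)
  ts <- seq(0, 9, by = 0.31)
  expect_equal(drive_current(ts, d1), 2.3 * sin(2 * pi * 0.4 * ts))
})

test_that("vector field matches hand evaluation and vanishes at equilibria", {
  p <- hr_params(k = 1)
  expect_equal(hr_vector_field(0, c(0, 1, 0), p, hr_drive()),
               c(dx = 1, dy = 0, dphi = 0))
  # state (1, -4, 1) with instantaneous drive 2: residual from the
  # rounded root eta = 1
  d <- hr_drive(A1 = 1, f1 = 0.05, A2 = 1, f2 = 0.05)
  expect_equal(hr_vector_field(5, c(1, -4, 1), p, d),
               c(dx = 0.01, dy = 0, dphi = 0))
  # exact roots are fixed points of the frozen-drive field
  for (I in c(-2, 0, 0.7, 2)) {
    eq <- solve_equilibria(1, I)
    for (r in eq$reports) {
      # zero-amplitude drive, then add the frozen instantaneous current
      f <- hr_vector_field(0, r$point, p, hr_drive()) + c(I, 0, 0)
      expect_lt(sqrt(sum(f^2)), 1e-9)
    }
  }
})

test_that("drive contribution flips sign after half a period", {
  p <- hr_params(k = 2.5)
  f <- 0.2
  d <- hr_drive(A1 = 1.7, f1 = f, A2 = 0.4, f2 = f)
  s <- c(0.3, -1.2, 0.8)
  for (t in c(0, 0.62, 3.1)) {
    auto <- hr_vector_field(t, s, p, hr_drive(A1 = 0, A2 = 0))
    v1 <- hr_vector_field(t, s, p, d) - auto
    v2 <- hr_vector_field(t + 1 / (2 * f), s, p, d) - auto
    expect_equal(v1, -v2)
  }
})

test_that("equilibrium Jacobian matches the closed form", {
  expect_equal(hr_jacobian(1, hr_params(k = 1)),
               matrix(c(3.01, 1, 0.02, -10, -1, 0, 1, 0, -1),
                      nrow = 3, byrow = TRUE))
  expect_equal(hr_jacobian(0, hr_params(k = 1)),
               matrix(c(0, 1, 0, 0, -1, 0, 1, 0, -1),
                      nrow = 3, byrow = TRUE))
  # alpha enters entry (1,1) through k * W(phi) only
  J <- hr_jacobian(2, hr_params(k = 3, alpha = 0.5))
  expect_equal(J[1, 1], 2 * 3 * 2 - 3 * 4 + 3 * (0.5 + 0.01 * 4))
})

test_that("-1 is always an eigenvalue and the state form agrees", {
  set.seed(42)
  for (i in 1:50) {
    eta <- runif(1, -5, 5)
    k <- runif(1, -20, 100)
    p <- hr_params(k = k)
    J <- hr_jacobian(eta, p)
    eig <- eigen(J, only.values = TRUE)$values
    expect_lt(min(abs(eig + 1)), 1e-9)
    # general-state Jacobian at x = phi = eta is the same matrix
    expect_equal(hr_jacobian(c(eta, runif(1, -10, 10), eta), p), J,
                 tolerance = 1e-12)
  }
})

test_that("parameter configs round-trip through JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  p <- hr_params(k = -7, beta = 0.02)
  d <- hr_drive(A1 = 3, f1 = 0.5, A2 = 1, f2 = 0.07)
  hr_write_config(path, p, d, ic = c(-5, 0, 0))
  got <- hr_read_config(path)
  expect_equal(got$params, p)
  expect_equal(got$drive, d)
  expect_equal(unname(got$ic), c(-5, 0, 0))
})
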
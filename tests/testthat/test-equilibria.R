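test_that("equilibrium cubic coefficients follow the frozen-drive reduction", {
  cc <- cubic_coefficients(k = 1, I_total = 2)
  expect_equal(cc[c("A", "B", "C", "D")],
               list(A = -0.99, B = -2, C = 0, D = 3))
  expect_false(cc$degenerate)
  expect_equal(cubic_coefficients(0, 0)[c("A", "B", "C", "D")],
               list(A = -1, B = -2, C = 0, D = 1))
  expect_true(cubic_coefficients(100, 0.3)$degenerate)
  # k * alpha enters the linear coefficient
  expect_equal(cubic_coefficients(2, 0, hr_params(alpha = 0.3))$C, 0.6)
})

test_that("depressed-cubic coefficients match the model-specific forms", {
  set.seed(7)
  for (i in 1:25) {
    k <- runif(1, -20, 90)
    I <- runif(1, -6, 6)
    cc <- cubic_coefficients(k, I)
    cd <- cardano_discriminant(cc)
    A <- 0.01 * k - 1
    expect_equal(cd$p, -4 / (3 * A^2), tolerance = 1e-12)
    expect_equal(cd$q, (I + 1) / A - 16 / (27 * A^3), tolerance = 1e-12)
    expect_equal(cd$delta, cd$q^2 / 4 + cd$p^3 / 27, tolerance = 1e-12)
  }
})

test_that("discriminant trichotomy matches brute-force root counting", {
  cd <- cardano_discriminant(cubic_coefficients(1, 2))
  expect_gt(cd$delta, 0)
  expect_identical(cd$n_real_roots, 1L)
  # boundary: p = q = 0 (pure cube) counts as the two-root case
  cd0 <- cardano_discriminant(list(A = 1, B = 0, C = 0, D = 0,
                                   degenerate = FALSE))
  expect_identical(cd0$n_real_roots, 2L)
  for (case in list(c(1, -2), c(1, 0.2), c(-30, 0), c(50, -1))) {
    cc <- cubic_coefficients(case[1], case[2])
    cd <- cardano_discriminant(cc)
    n_oracle <- length(oracle_cubic_roots(cc$A, cc$B, cc$C, cc$D))
    if (cd$n_real_roots == 1L) expect_identical(n_oracle, 1L)
    if (cd$n_real_roots == 3L) expect_identical(n_oracle, 3L)
  }
  expect_error(cardano_discriminant(cubic_coefficients(100, 0)),
               "degenerate")
})

test_that("closed-form roots agree with the bisection oracle", {
  # printed scenario: single root near 1 at I = +2, near -2.22 at I = -2
  eq <- solve_equilibria(1, 2)
  expect_length(eq$reports, 1)
  expect_equal(eq$reports[[1]]$eta, 1, tolerance = 0.01)
  expect_lt(abs(eq$reports[[1]]$residual), 1e-12)
  eq2 <- solve_equilibria(1, -2)
  expect_equal(eq2$reports[[1]]$eta, -2.22, tolerance = 0.01)
  # randomized sweep against the oracle
  set.seed(11)
  worst <- 0
  for (i in 1:1000) {
    k <- runif(1, -20, 90)
    I <- runif(1, -6, 6)
    cc <- cubic_coefficients(k, I)
    got <- vapply(solve_equilibria(k, I)$reports, `[[`, numeric(1), "eta")
    want <- oracle_cubic_roots(cc$A, cc$B, cc$C, cc$D)
    expect_length(got, length(want))
    worst <- max(worst, max(abs(sort(got) - want)))
  }
  expect_lt(worst, 1e-8)
})

test_that("degenerate k = 100 cubic falls back to the quadratic", {
  eq <- solve_equilibria(100, 0.5)
  etas <- vapply(eq$reports, `[[`, numeric(1), "eta")
  expect_equal(sort(etas), c(-1, 1) * sqrt(1.5 / 2))
  expect_error(solve_equilibria(100, -3), "no real equilibrium")
})

test_that("characteristic coefficients match the printed rational forms", {
  expect_equal(characteristic_coeffs(1, 1)[["m1"]], -1.01)
  expect_equal(characteristic_coeffs(0, 37),
               c(m1 = 2, m2 = 1, m3 = 0))
  set.seed(5)
  for (i in 1:25) {
    eta <- runif(1, -4, 4)
    k <- runif(1, -20, 100)
    m <- characteristic_coeffs(eta, k)
    expect_equal(m[["m1"]],
                 (200 - 600 * eta + 300 * eta^2 - k * eta^2) / 100,
                 tolerance = 1e-10)
    expect_equal(m[["m2"]],
                 (600 * eta^2 - 4 * k * eta^2 - 200 * eta + 100) / 100,
                 tolerance = 1e-10)
    expect_equal(m[["m3"]],
                 (400 * eta + 300 * eta^2 - 3 * k * eta^2) / 100,
                 tolerance = 1e-10)
    # (lambda + 1) factor identity
    expect_equal(m[["m2"]], m[["m1"]] + m[["m3"]] - 1, tolerance = 1e-12)
  }
})

test_that("eigenvalues agree with a dense solve and carry -1", {
  eig <- eigenvalues_at(0, 12)
  expect_equal(sort(Re(eig)), c(-1, -1, 0))
  set.seed(3)
  for (i in 1:20) {
    eta <- runif(1, -4, 4)
    k <- runif(1, -20, 100)
    eig <- eigenvalues_at(eta, k)
    dense <- eigen(hr_jacobian(eta, hr_params(k = k)))$values
    expect_equal(sort(Re(eig)), sort(Re(dense)), tolerance = 1e-8)
    expect_lt(min(abs(eig + 1)), 1e-9)
    expect_true(all(diff(Re(eig)) <= 1e-12))  # sorted by real part
  }
})

test_that("stability labels follow the strict negative-real-part rule", {
  expect_identical(classify_stability(eigenvalues_at(1, 1)), "unstable")
  expect_identical(classify_stability(eigenvalues_at(-2.02, 1)), "stable")
  expect_identical(classify_stability(c(-1, -1, 0)), "unstable")
  expect_identical(classify_stability(c(-1, -2, -1e-12)), "unstable")
})

test_that("equilibrium track reproduces the tabulated stability switch", {
  p <- hr_params(k = 1)
  d <- hr_drive(A1 = 1, f1 = 0.05, A2 = 1, f2 = 0.05)
  tr <- equilibrium_track(p, d, t_grid = c(5, 15, 25))
  expect_identical(tr$stability[tr$t == 5], "unstable")
  expect_identical(tr$stability[tr$t == 15], "stable")
  expect_identical(tr$stability[tr$t == 25], "unstable")
  # the flag changes exactly where the leading real part crosses zero
  dense <- equilibrium_track(p, d, t_grid = seq(5, 25, by = 0.01))
  expect_identical(dense$stability == "stable", dense$max_re < -1e-9)
  iv <- stability_intervals(dense)
  stable <- iv[iv$stability == "stable", ]
  expect_equal(nrow(stable), 1)
  expect_lt(abs(stable$t_start - 11.64), 0.05)
  expect_lt(abs(stable$t_end - 18.34), 0.05)
})
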
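# Independent brute-force root finder for A x^3 + B x^2 + C x + D:
# sign changes on a fine grid inside a Cauchy bound, refined by uniroot.
oracle_cubic_roots <- function(A, B, C, D, n_grid = 40001) {
  P <- function(x) ((A * x + B) * x + C) * x + D
  bound <- 1 + max(abs(c(B, C, D))) / abs(A)
  xs <- seq(-bound, bound, length.out = n_grid)
  ys <- P(xs)
  sgn <- sign(ys)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  roots <- vapply(flips, function(i)
    stats::uniroot(P, c(xs[i], xs[i + 1]), tol = 1e-13)$root, numeric(1))
  exact <- xs[ys == 0]
  sort(unique(c(roots, exact)))
}

# Synthetic trace of Gaussian bumps on a flat baseline
bump_trajectory <- function(centers, amp = 2, width = 0.2, baseline = 0,
                            t_end = max(centers) + 5, dt = 0.01) {
  t <- seq(0, t_end, by = dt)
  x <- rep(baseline, length(t))
  for (ct in centers) x <- x + amp * exp(-(t - ct)^2 / (2 * width^2))
  as_hr_trajectory(t, cbind(x, 0, 0))
}

# Combined state+tangent stepper for an arbitrary R-function system,
# for exercising lyapunov_qr() on flows with known spectra.
rfun_var_stepper <- function(f, jac) {
  function(y, t0, t1) {
    n <- (sqrt(4 * length(y) + 1) - 1) / 2
    n <- round(n)
    deriv <- function(t, yy, parms) {
      s <- yy[seq_len(n)]
      V <- matrix(yy[-seq_len(n)], n, n)
      list(c(f(t, s), as.vector(jac(t, s) %*% V)))
    }
    out <- deSolve::ode(y = y, times = c(t0, t1), func = deriv,
                        parms = NULL, method = "ode45",
                        rtol = 1e-10, atol = 1e-12)
    out[2, -1]
  }
}

# canonical scenario shortcuts used across test files
params_k1 <- function() hr_params(k = 1)
drive_hilo <- function(f2) hr_drive(A1 = 3, f1 = 0.5, A2 = 3, f2 = f2)
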
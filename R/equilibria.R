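#' Coefficients of the instantaneous equilibrium cubic
#'
#' Setting the vector field to zero (with the drive frozen at its
#' instantaneous value `I_total`) gives \eqn{y = c - d\eta^2},
#' \eqn{\phi = \eta}, and a cubic in the membrane potential \eqn{\eta}:
#' \deqn{P(\eta) = (k\beta - b)\eta^3 + (a - d)\eta^2 + k\alpha\,\eta +
#'   c + I = 0}
#' With the canonical parameters this is
#' \eqn{(0.01k - 1)\eta^3 - 2\eta^2 + 1 + I = 0}.
#'
#' @param k Memristor coupling strength.
#' @param I_total Instantaneous total drive current.
#' @param params An [hr_params()] object; its `k` is overridden by the
#'   `k` argument.
#' @return List with coefficients `A`, `B`, `C`, `D` of
#'   \eqn{A\eta^3 + B\eta^2 + C\eta + D} and a logical `degenerate`
#'   (`TRUE` when `A` vanishes, e.g. `k = 100` with defaults).
#' @examples
#' cubic_coefficients(k = 1, I_total = 2)   # A = -0.99, B = -2, C = 0, D = 3
#' @export
cubic_coefficients <- function(k, I_total, params = hr_params()) {
  params$k <- k
  A <- params$k * params$beta - params$b
  B <- params$a - params$d
  C <- params$k * params$alpha
  D <- params$c + I_total
  list(A = A, B = B, C = C, D = D,
       degenerate = abs(A) <= 1e-12 * max(1, abs(B), abs(C), abs(D)))
}

#' Cardano discriminant and real-root count of a cubic
#'
#' For \eqn{A\eta^3 + B\eta^2 + C\eta + D} the depressed-cubic
#' coefficients are \eqn{p = (3AC - B^2)/(3A^2)},
#' \eqn{q = (27A^2 D - 9ABC + 2B^3)/(27A^3)} and the discriminant is
#' \eqn{\Delta = q^2/4 + p^3/27}.  One real root when \eqn{\Delta > 0},
#' three when \eqn{\Delta < 0}, two (a double root) when
#' \eqn{\Delta = 0}.  Equality is resolved with the relative tolerance
#' \eqn{|\Delta| \le 10^{-12}\max(1, q^2)} so the boundary case is
#' reachable in floating point.
#'
#' @param cubic A coefficient list as returned by [cubic_coefficients()].
#' @return List of class `hr_cardano` with `p`, `q`, `delta`,
#'   `n_real_roots`.
#' @export
cardano_discriminant <- function(cubic) {
  if (isTRUE(cubic$degenerate))
    stop("degenerate cubic (leading coefficient 0): use the quadratic path ",
         "via solve_equilibria()")
  A <- cubic$A; B <- cubic$B; C <- cubic$C; D <- cubic$D
  p <- (3 * A * C - B^2) / (3 * A^2)
  q <- (27 * A^2 * D - 9 * A * B * C + 2 * B^3) / (27 * A^3)
  delta <- q^2 / 4 + p^3 / 27
  n <- if (abs(delta) <= 1e-12 * max(1, q^2)) 2L else if (delta > 0) 1L else 3L
  structure(list(p = p, q = q, delta = delta, n_real_roots = n),
            class = "hr_cardano")
}

# One closed-form real-root solve of the depressed cubic t^3 + p t + q,
# shifted back by -B/(3A).  Delta < 0 uses the trigonometric
# three-real-root form to avoid complex cube-root branch cuts.
cardano_real_roots <- function(cubic, card = cardano_discriminant(cubic)) {
  p <- card$p; q <- card$q; delta <- card$delta
  shift <- -cubic$B / (3 * cubic$A)
  if (card$n_real_roots == 1L) {
    s <- sqrt(delta)
    u <- cbrt(-q / 2 + s)
    v <- cbrt(-q / 2 - s)
    roots <- u + v + shift
  } else if (card$n_real_roots == 3L) {
    r <- sqrt(-p / 3)
    arg <- max(-1, min(1, 3 * q / (2 * p) * sqrt(-3 / p)))
    theta <- acos(arg)
    roots <- 2 * r * cos(theta / 3 - 2 * pi * (0:2) / 3) + shift
  } else {                               # delta == 0: double + simple root
    if (abs(p) <= 1e-14 && abs(q) <= 1e-14) {
      roots <- c(shift, shift)           # triple root, reported per the
    } else {                             # two-real-root convention
      roots <- c(3 * q / p, -3 * q / (2 * p)) + shift
    }
  }
  sort(unique(roots))
}

cbrt <- function(x) sign(x) * abs(x)^(1 / 3)

# Newton polish of a root of A x^3 + B x^2 + C x + D
polish_root <- function(x, cubic, steps = 3L) {
  for (i in seq_len(steps)) {
    f <- ((cubic$A * x + cubic$B) * x + cubic$C) * x + cubic$D
    df <- (3 * cubic$A * x + 2 * cubic$B) * x + cubic$C
    if (abs(df) < 1e-300) break
    x <- x - f / df
  }
  x
}

#' Solve the instantaneous equilibrium problem
#'
#' Computes every real equilibrium of the model with the drive frozen at
#' `I_total`: roots \eqn{\eta} of the equilibrium cubic (Cardano closed
#' form, polished by Newton steps), the full points
#' \eqn{E = (\eta, c - d\eta^2, \eta)}, characteristic-polynomial
#' coefficients, eigenvalues, and a stability label.  The `k = 100`
#' degeneracy (vanishing cubic leading coefficient with default
#' parameters) falls back to the quadratic; a linear sub-case without a
#' real root is an error.
#'
#' @inheritParams cubic_coefficients
#' @return Object of class `hr_equilibrium_set`: a list with the
#'   `cardano` report (or `NULL` in the degenerate case) and `reports`,
#'   one per real root, each holding `eta`, `point`, `m` (m1, m2, m3),
#'   `eigenvalues` (sorted by decreasing real part), `stability`, and the
#'   cubic residual at `eta`.
#' @examples
#' solve_equilibria(k = 1, I_total = 2)    # single unstable focus near eta = 1
#' @export
solve_equilibria <- function(k, I_total, params = hr_params()) {
  params$k <- k
  cubic <- cubic_coefficients(k, I_total, params)
  card <- NULL
  if (cubic$degenerate) {
    # B eta^2 + C eta + D = 0
    if (abs(cubic$B) > 1e-14) {
      disc <- cubic$C^2 - 4 * cubic$B * cubic$D
      if (disc < 0) roots <- numeric(0)
      else roots <- sort(unique((-cubic$C + c(-1, 1) * sqrt(disc)) /
                                  (2 * cubic$B)))
    } else if (abs(cubic$C) > 1e-14) {
      roots <- -cubic$D / cubic$C
    } else {
      stop("no real equilibrium: cubic degenerates to a constant")
    }
    if (length(roots) == 0)
      stop("no real equilibrium in the degenerate quadratic case")
  } else {
    card <- cardano_discriminant(cubic)
    roots <- vapply(cardano_real_roots(cubic, card), polish_root,
                    numeric(1), cubic = cubic)
    roots <- sort(unique(roots))
  }
  reports <- lapply(roots, function(eta) {
    eig <- eigenvalues_at(eta, k, params)
    resid <- ((cubic$A * eta + cubic$B) * eta + cubic$C) * eta + cubic$D
    list(eta = eta,
         point = c(x = eta, y = params$c - params$d * eta^2, phi = eta),
         m = characteristic_coeffs(eta, k, params),
         eigenvalues = eig,
         stability = classify_stability(eig),
         residual = resid)
  })
  structure(list(k = k, I_total = I_total, cubic = cubic, cardano = card,
                 reports = reports),
            class = "hr_equilibrium_set")
}

#' @export
print.hr_equilibrium_set <- function(x, ...) {
  cat("<hr_equilibrium_set>  k =", x$k, " I_total =", x$I_total, "\n")
  if (!is.null(x$cardano))
    cat("  Delta =", format(x$cardano$delta),
        " n_real_roots =", x$cardano$n_real_roots, "\n")
  for (r in x$reports) {
    cat(sprintf("  eta = %+.6f  E = (%.4f, %.4f, %.4f)  %s\n",
                r$eta, r$point[1], r$point[2], r$point[3], r$stability))
    cat("    eigenvalues:", paste(format(r$eigenvalues, digits = 6),
                                  collapse = ", "), "\n")
  }
  invisible(x)
}

#' Characteristic-polynomial coefficients at an equilibrium
#'
#' Coefficients \eqn{(m_1, m_2, m_3)} of
#' \eqn{\lambda^3 + m_1\lambda^2 + m_2\lambda + m_3} for the equilibrium
#' Jacobian, computed as \eqn{m_1 = -\mathrm{tr}\,J}, \eqn{m_2 =} sum of
#' principal 2x2 minors, \eqn{m_3 = -\det J}.  The \eqn{(\lambda + 1)}
#' factor of the spectrum forces the identity
#' \eqn{m_2 = m_1 + m_3 - 1}.
#'
#' @param eta Equilibrium root.
#' @param k Memristor coupling strength.
#' @param params An [hr_params()] object.
#' @return Named numeric vector `(m1, m2, m3)`.
#' @export
characteristic_coeffs <- function(eta, k, params = hr_params()) {
  params$k <- k
  J <- hr_jacobian(eta, params)
  m1 <- -sum(diag(J))
  minor <- function(i, j) det(J[c(i, j), c(i, j)])
  m2 <- minor(1, 2) + minor(1, 3) + minor(2, 3)
  m3 <- -det(J)
  c(m1 = m1, m2 = m2, m3 = m3)
}

#' Eigenvalues of the equilibrium Jacobian
#'
#' @inheritParams characteristic_coeffs
#' @return Complex length-3 vector sorted by decreasing real part (ties
#'   by decreasing imaginary part).  `-1` is always in the spectrum.
#' @examples
#' eigenvalues_at(1, k = 1)        # 1.005 +- 2.4413i and -1
#' @export
eigenvalues_at <- function(eta, k, params = hr_params()) {
  params$k <- k
  eig <- eigen(hr_jacobian(eta, params), only.values = TRUE)$values
  eig <- as.complex(eig)
  eig[order(-Re(eig), -Im(eig))]
}

#' Classify equilibrium stability from eigenvalues
#'
#' Stable iff every real part is below `-tol`; anything else (including
#' marginal and mixed-sign/saddle spectra) is labeled unstable, matching
#' the convention that any non-negative real part destabilizes the
#' point.  The sign pattern is available from the eigenvalues themselves
#' for callers wanting the finer taxonomy.
#'
#' @param eigs Complex (or numeric) vector of eigenvalues.
#' @param tol Strictness margin (default 1e-9).
#' @return `"stable"` or `"unstable"`.
#' @export
classify_stability <- function(eigs, tol = 1e-9) {
  if (all(Re(eigs) < -tol)) "stable" else "unstable"
}

#' Track equilibria and their stability over time
#'
#' For every time in `t_grid` the drive is frozen at its instantaneous
#' value, the equilibrium cubic solved, and each real root classified.
#'
#' @param params An [hr_params()] object.
#' @param drive An [hr_drive()] object.
#' @param t_grid Increasing numeric time vector.
#' @return A data frame of class `hr_equilibrium_track` with columns
#'   `t`, `root_id`, `eta`, `re_lambda1..3` (decreasing), `max_re`
#'   (largest real part excluding none), and `stability`.
#' @examples
#' tr <- equilibrium_track(hr_params(k = 1),
#'                         hr_drive(A1 = 1, f1 = 0.05, A2 = 1, f2 = 0.05),
#'                         t_grid = c(5, 15, 25))
#' @export
equilibrium_track <- function(params, drive, t_grid) {
  stopifnot(is.numeric(t_grid), all(is.finite(t_grid)),
            all(diff(t_grid) > 0) || length(t_grid) == 1L)
  rows <- lapply(t_grid, function(t) {
    I <- drive_current(t, drive)
    eq <- solve_equilibria(params$k, I, params)
    do.call(rbind, lapply(seq_along(eq$reports), function(i) {
      r <- eq$reports[[i]]
      re <- sort(Re(r$eigenvalues), decreasing = TRUE)
      data.frame(t = t, root_id = i, eta = r$eta,
                 re_lambda1 = re[1], re_lambda2 = re[2], re_lambda3 = re[3],
                 max_re = re[1], stability = r$stability)
    }))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("hr_equilibrium_track", "data.frame")
  out
}

#' Contiguous stability intervals of an equilibrium track
#'
#' Summarizes an [equilibrium_track()] into runs of constant stability of
#' the most-unstable root at each time.
#'
#' @param track An `hr_equilibrium_track` data frame.
#' @return Data frame with `t_start`, `t_end`, `stability`.
#' @export
stability_intervals <- function(track) {
  # a time is labeled stable only when every instantaneous root is
  # stable (in the multi-root window an unstable branch coexists)
  agg <- vapply(split(track, track$t),
                function(d) all(d$stability == "stable"), logical(1))
  t <- as.numeric(names(agg))
  o <- order(t); t <- t[o]; agg <- agg[o]
  r <- rle(agg)
  idx_end <- cumsum(r$lengths)
  idx_start <- c(1, head(idx_end, -1) + 1)
  data.frame(t_start = t[idx_start], t_end = t[idx_end],
             stability = ifelse(r$values, "stable", "unstable"))
}
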
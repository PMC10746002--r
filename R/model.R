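#' Model parameters for the memristive Hindmarsh-Rose neuron
#'
#' The model couples the two-variable Hindmarsh-Rose equations to a
#' flux-controlled memristor whose memductance is \eqn{W(\phi) = \alpha +
#' \beta \phi^2}.  The membrane equation receives the induction current
#' \eqn{k W(\phi) x} plus up to two sinusoidal drive currents:
#' \deqn{\dot x = y + a x^2 - b x^3 + k W(\phi) x + I_1(t) + I_2(t)}
#' \deqn{\dot y = c - d x^2 - y}
#' \deqn{\dot \phi = x - \phi}
#'
#' @param a,b,c,d Dimensionless Hindmarsh-Rose coefficients (defaults
#'   3, 1, 1, 5).
#' @param k Memristor coupling strength (dimensionless; may be negative).
#' @param alpha,beta Memductance coefficients of \eqn{W(\phi)};
#'   defaults 0 and 0.01.
#' @return An object of class `hr_params` (named list).
#' @examples
#' p <- hr_params()          # canonical parameter set, k = 1
#' hr_params(k = -7)         # multistability-elimination regime
#' @export
hr_params <- function(a = 3, b = 1, c = 1, d = 5, k = 1,
                      alpha = 0, beta = 0.01) {
  p <- list(a = a, b = b, c = c, d = d, k = k, alpha = alpha, beta = beta)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number")
  }
  if (beta < 0) stop("'beta' must be non-negative")
  structure(p, class = "hr_params")
}

#' Sinusoidal drive currents
#'
#' Two superimposed AC sources \eqn{I_1 = A_1 \sin(2\pi f_1 t)} and
#' \eqn{I_2 = A_2 \sin(2\pi f_2 t)}.  Single excitation is encoded as
#' `A2 = 0`.
#'
#' @param A1,A2 Drive amplitudes (dimensionless).
#' @param f1,f2 Drive frequencies (cycles per unit time, >= 0).
#' @return An object of class `hr_drive` (named list).
#' @examples
#' hr_drive(A1 = 3, f1 = 0.5)                  # single excitation
#' hr_drive(A1 = 3, f1 = 0.5, A2 = 3, f2 = 0.07)  # high-low frequency pair
#' @export
hr_drive <- function(A1 = 0, f1 = 0.5, A2 = 0, f2 = 0.05) {
  dv <- list(A1 = A1, f1 = f1, A2 = A2, f2 = f2)
  for (nm in names(dv)) {
    v <- dv[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("drive field '", nm, "' must be a single finite number")
  }
  if (f1 < 0 || f2 < 0) stop("drive frequencies must be >= 0")
  structure(dv, class = "hr_drive")
}

#' @export
print.hr_params <- function(x, ...) {
  cat("<hr_params>  a =", x$a, " b =", x$b, " c =", x$c, " d =", x$d,
      "\n             k =", x$k, " alpha =", x$alpha, " beta =", x$beta, "\n")
  invisible(x)
}

#' @export
print.hr_drive <- function(x, ...) {
  cat("<hr_drive>  I1: A1 =", x$A1, " f1 =", x$f1,
      "   I2: A2 =", x$A2, " f2 =", x$f2, "\n")
  invisible(x)
}

# parameter vector in the order the compiled code expects
as_parms_vector <- function(params, drive) {
  c(params$a, params$b, params$c, params$d, params$k,
    params$alpha, params$beta,
    drive$A1, drive$f1, drive$A2, drive$f2)
}

check_state <- function(state) {
  if (!is.numeric(state) || length(state) != 3L || any(!is.finite(state)))
    stop("state must be a finite numeric vector (x, y, phi)")
  state <- as.numeric(state)
  names(state) <- c("x", "y", "phi")
  state
}

#' Memductance of the flux-controlled memristor
#'
#' @param phi Magnetic flux (numeric vector allowed).
#' @param params An [hr_params()] object supplying `alpha` and `beta`.
#' @return \eqn{W(\phi) = \alpha + \beta \phi^2}.
#' @examples
#' memductance(1, hr_params())   # 0.01
#' @export
memductance <- function(phi, params = hr_params()) {
  stopifnot(is.numeric(phi), all(is.finite(phi)))
  params$alpha + params$beta * phi^2
}

#' Total injected drive current at time t
#'
#' @param t Time (numeric vector allowed).
#' @param drive An [hr_drive()] object.
#' @return \eqn{A_1 \sin(2\pi f_1 t) + A_2 \sin(2\pi f_2 t)}.
#' @examples
#' drive_current(5, hr_drive(A1 = 1, f1 = 0.05, A2 = 1, f2 = 0.05))  # 2
#' @export
drive_current <- function(t, drive) {
  stopifnot(is.numeric(t), all(is.finite(t)))
  drive$A1 * sin(2 * pi * drive$f1 * t) + drive$A2 * sin(2 * pi * drive$f2 * t)
}

#' Vector field of the forced memristive neuron
#'
#' Evaluates \eqn{(\dot x, \dot y, \dot \phi)} at time `t`.  Time enters
#' only through the drive; the system is treated in non-autonomous form.
#'
#' @param t Time.
#' @param state Numeric length-3 state `(x, y, phi)`.
#' @param params An [hr_params()] object.
#' @param drive An [hr_drive()] object.
#' @return Named numeric vector `(dx, dy, dphi)`.
#' @export
hr_vector_field <- function(t, state, params = hr_params(),
                            drive = hr_drive()) {
  s <- check_state(state)
  x <- s[["x"]]; y <- s[["y"]]; phi <- s[["phi"]]
  I <- drive_current(t, drive)
  c(dx = y + params$a * x^2 - params$b * x^3 +
      params$k * memductance(phi, params) * x + I,
    dy = params$c - params$d * x^2 - y,
    dphi = x - phi)
}

#' Jacobian of the model
#'
#' With a full state `(x, y, phi)` the general Jacobian of the autonomous
#' part is returned.  A scalar argument `eta` is interpreted as the
#' equilibrium convention `x = phi = eta` (the equilibrium line of the
#' model), which yields entries
#' \eqn{J_{11} = 2a\eta - 3b\eta^2 + k(\alpha + \beta\eta^2)},
#' \eqn{J_{13} = 2 k \beta \eta^2}.
#'
#' @param state_or_eta Length-3 state, or a scalar equilibrium root
#'   \eqn{\eta}.
#' @param params An [hr_params()] object.
#' @return A 3x3 numeric matrix.  `-1` is always an eigenvalue: rows 2
#'   and 3 of `J + I` are multiples of the first basis vector.
#' @examples
#' hr_jacobian(1, hr_params(k = 1))
#' @export
hr_jacobian <- function(state_or_eta, params = hr_params()) {
  if (length(state_or_eta) == 1L) {
    eta <- as.numeric(state_or_eta)
    stopifnot(is.finite(eta))
    s <- c(eta, 0, eta)
  } else {
    s <- check_state(state_or_eta)
  }
  x <- s[[1]]; phi <- s[[3]]
  matrix(c(
    2 * params$a * x - 3 * params$b * x^2 +
      params$k * (params$alpha + params$beta * phi^2), 1, 2 * params$k * params$beta * phi * x,
    -2 * params$d * x, -1, 0,
    1, 0, -1), nrow = 3, byrow = TRUE)
}

#' Read or write a flat parameter configuration (JSON)
#'
#' Serializes a parameter/drive pair (plus optional initial condition) to
#' a flat key-value JSON file, the interchange format used by the
#' command-line interface.
#'
#' @param params,drive Model objects to write.
#' @param ic Optional initial condition (length-3 numeric).
#' @param path File path.
#' @return `hr_write_config` returns `path` invisibly; `hr_read_config`
#'   returns `list(params, drive, ic)`.
#' @export
hr_write_config <- function(path, params = hr_params(), drive = hr_drive(),
                            ic = NULL) {
  x <- c(unclass(params), unclass(drive))
  if (!is.null(ic)) {
    ic <- check_state(ic)
    x <- c(x, list(x0 = ic[["x"]], y0 = ic[["y"]], phi0 = ic[["phi"]]))
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname hr_write_config
#' @export
hr_read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- hr_params(a = x$a, b = x$b, c = x$c, d = x$d, k = x$k,
                      alpha = x$alpha, beta = x$beta)
  drive <- hr_drive(A1 = x$A1, f1 = x$f1, A2 = x$A2, f2 = x$f2)
  ic <- if (!is.null(x$x0)) c(x = x$x0, y = x$y0, phi = x$phi0) else NULL
  list(params = params, drive = drive, ic = ic)
}
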
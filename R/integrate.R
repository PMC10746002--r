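#' Integrate the forced memristive neuron
#'
#' Adaptive Dormand-Prince 4(5) integration (deSolve's `ode45`) of the
#' non-autonomous system, with a compiled right-hand side.  The maximum
#' internal step is capped at
#' `min(1/(20 f1), 1/(20 f2), 0.1)` (active drives only) so the
#' sinusoidal forcing is always resolved.  Output is sampled on a
#' uniform grid of spacing `sample_dt`.  The integration is fully
#' deterministic: identical inputs give bit-identical trajectories.
#'
#' @param params An [hr_params()] object.
#' @param drive An [hr_drive()] object.
#' @param ic Initial condition, numeric `(x, y, phi)`.
#' @param t_span Length-2 numeric `(t0, t1)`, `t1 > t0`.
#' @param rtol,atol Relative/absolute tolerances (defaults 1e-8, 1e-10;
#'   chosen so periodic-orbit peak amplitudes are stable to 4 decimals).
#' @param sample_dt Output sampling interval (default 0.01).
#' @param max_step Optional override of the internal step cap.
#' @return Object of class `hr_trajectory`: list with `t`, `states`
#'   (matrix with columns `x`, `y`, `phi`), and `meta` recording all
#'   inputs (sufficient to re-run the integration bit-identically).
#' @examples
#' \donttest{
#' tr <- hr_integrate(hr_params(), hr_drive(A1 = 3, f1 = 0.5),
#'                    ic = c(-5, 0, 0), t_span = c(0, 100))
#' }
#' @export
hr_integrate <- function(params, drive, ic, t_span = c(0, 2000),
                         rtol = 1e-8, atol = 1e-10, sample_dt = 0.01,
                         max_step = NULL) {
  stopifnot(length(t_span) == 2L, t_span[2] > t_span[1],
            rtol > 0, atol > 0, sample_dt > 0)
  ic <- check_state(ic)
  if (is.null(max_step)) max_step <- default_max_step(drive)
  times <- seq(t_span[1], t_span[2], by = sample_dt)
  out <- deSolve::ode(y = ic, times = times, func = "memhr_derivs",
                      parms = as_parms_vector(params, drive),
                      dllname = "memhr", initfunc = "memhr_init",
                      method = "ode45", rtol = rtol, atol = atol,
                      hmax = max_step, maxsteps = 1e5)
  if (nrow(out) < length(times) || any(!is.finite(out)))
    stop("integration failure near t = ",
         format(out[max(1, nrow(out)), 1]),
         " (non-finite state or step-size underflow)")
  structure(list(t = out[, 1], states = unname(out[, 2:4, drop = FALSE]),
                 meta = list(params = params, drive = drive, ic = ic,
                             t_span = t_span, rtol = rtol, atol = atol,
                             sample_dt = sample_dt, max_step = max_step,
                             t_cut = NA_real_)),
            class = "hr_trajectory")
}

default_max_step <- function(drive) {
  h <- 0.1
  if (drive$A1 != 0 && drive$f1 > 0) h <- min(h, 1 / (20 * drive$f1))
  if (drive$A2 != 0 && drive$f2 > 0) h <- min(h, 1 / (20 * drive$f2))
  h
}

#' Construct a trajectory object from precomputed series
#'
#' Wraps arbitrary time series in the container used throughout the
#' package, e.g. to run the spike/burst analyses on synthetic or external
#' data.
#'
#' @param t Strictly increasing time vector.
#' @param states Numeric matrix (or vector for `x` only) with columns
#'   `x`, `y`, `phi`; missing columns are zero-filled.
#' @param meta Optional metadata list.
#' @return An `hr_trajectory` object.
#' @export
as_hr_trajectory <- function(t, states, meta = list()) {
  stopifnot(is.numeric(t), all(diff(t) > 0))
  if (is.vector(states)) states <- cbind(states, 0, 0)
  states <- as.matrix(states)
  if (ncol(states) == 1L) states <- cbind(states, 0, 0)
  stopifnot(nrow(states) == length(t), ncol(states) == 3L,
            all(is.finite(states)))
  meta$sample_dt <- meta$sample_dt %||% stats::median(diff(t))
  meta$t_cut <- meta$t_cut %||% NA_real_
  structure(list(t = as.numeric(t), states = unname(states), meta = meta),
            class = "hr_trajectory")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.hr_trajectory <- function(x, ...) {
  cat("<hr_trajectory>  ", length(x$t), "samples, t in [",
      format(x$t[1]), ",", format(x$t[length(x$t)]), "]\n")
  if (!is.null(x$meta$params)) {
    cat("  k =", x$meta$params$k, "")
    cat(" A1 =", x$meta$drive$A1, " f1 =", x$meta$drive$f1,
        " A2 =", x$meta$drive$A2, " f2 =", x$meta$drive$f2, "\n")
  }
  if (!is.na(x$meta$t_cut)) cat("  transient cut at t =", x$meta$t_cut, "\n")
  invisible(x)
}

#' Discard the transient part of a trajectory
#'
#' @param traj An `hr_trajectory`.
#' @param t_cut Cut time; the suffix with `t >= t_cut` is kept.
#' @return The truncated `hr_trajectory` with the cut recorded in `meta`.
#' @export
discard_transient <- function(traj, t_cut) {
  stopifnot(inherits(traj, "hr_trajectory"))
  if (t_cut < traj$t[1] || t_cut > traj$t[length(traj$t)])
    stop("t_cut = ", t_cut, " outside trajectory range [",
         traj$t[1], ", ", traj$t[length(traj$t)], "]")
  keep <- traj$t >= t_cut
  traj$t <- traj$t[keep]
  traj$states <- traj$states[keep, , drop = FALSE]
  traj$meta$t_cut <- t_cut
  traj
}

# single adaptive step over [t0, t1] for an n-state compiled system;
# returns the final state only
ode_step <- function(y, t0, t1, parms, func, rtol, atol, hmax) {
  out <- deSolve::ode(y = y, times = c(t0, t1), func = func,
                      parms = parms, dllname = "memhr",
                      initfunc = "memhr_init", method = "ode45",
                      rtol = rtol, atol = atol, hmax = hmax,
                      maxsteps = 1e7)
  if (nrow(out) < 2L || any(!is.finite(out)))
    stop("integration failure in [", t0, ", ", t1, "]")
  out[2, -1]
}
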
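#' Bifurcation sweep over a drive or coupling parameter
#'
#' For every grid value of `param_name` (one of `A1`, `f1`, `f2`, `k`)
#' and every initial condition, the model is integrated, the transient
#' discarded, and the post-transient local maxima of `x` recorded as the
#' bifurcation ordinate (peak sampling; a stroboscopic option samples
#' `x` once per period of the swept/first drive instead).  The leading
#' Lyapunov exponent is computed per point.  Branches keep their
#' initial-condition identity; every grid point starts from the declared
#' initial condition (no state inheritance).
#'
#' @param param_name One of `"A1"`, `"f1"`, `"f2"`, `"k"`.
#' @param grid Increasing parameter grid.
#' @param ics List of initial conditions (one branch per entry).
#' @param params,drive Baseline model inputs; the swept entry is
#'   overridden.
#' @param t_end,transient Integration horizon and transient cut
#'   (defaults 500, 250).
#' @param compute_le Compute LE1 per point (default TRUE).
#' @param le_horizon Averaging horizon for the exponents (default 500).
#' @param ordinate `"peaks"` (default) or `"strobe"`.
#' @param sample_dt Output sampling interval (default 0.01).
#' @param ... Integrator tolerances.
#' @return Object of class `hr_bifurcation`: list of branches, each with
#'   `ic`, `samples` (long data frame `param_value`, `value`), `le1`
#'   (per grid point), and `failed` (logical per grid point; failures
#'   are recorded and the sweep continues).
#' @export
bifurcation_sweep <- function(param_name, grid, ics, params = hr_params(),
                              drive, t_end = 500, transient = 250,
                              compute_le = TRUE, le_horizon = 500,
                              ordinate = c("peaks", "strobe"),
                              sample_dt = 0.01, ...) {
  param_name <- match.arg(param_name, c("A1", "f1", "f2", "k"))
  ordinate <- match.arg(ordinate)
  stopifnot(all(diff(grid) > 0), is.list(ics))
  branches <- lapply(ics, function(ic) {
    samples <- vector("list", length(grid))
    le1 <- rep(NA_real_, length(grid))
    failed <- logical(length(grid))
    for (i in seq_along(grid)) {
      pd <- set_swept(params, drive, param_name, grid[i])
      res <- tryCatch({
        traj <- hr_integrate(pd$params, pd$drive, ic,
                             t_span = c(0, t_end),
                             sample_dt = sample_dt, ...)
        tail_traj <- discard_transient(traj, transient)
        vals <- if (ordinate == "peaks")
          detect_spikes(tail_traj, height_min = -Inf,
                        prominence_min = 0.05, min_separation = 0)$peaks
        else strobe_values(tail_traj, pd$drive)
        le <- if (compute_le)
          suppressWarnings(
            lyapunov_spectrum(pd$params, pd$drive, ic,
                              t_transient = transient,
                              t_horizon = le_horizon, ...)$exponents[1])
        else NA_real_
        list(vals = vals, le = le)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failed[i] <- TRUE
        samples[[i]] <- numeric(0)
      } else {
        samples[[i]] <- res$vals
        le1[i] <- res$le
      }
    }
    long <- data.frame(
      param_value = rep(grid, lengths(samples)),
      value = unlist(samples))
    list(ic = ic, samples = long, le1 = le1, failed = failed)
  })
  structure(list(param_name = param_name, grid = grid, branches = branches),
            class = "hr_bifurcation")
}

set_swept <- function(params, drive, param_name, value) {
  if (param_name == "k") params$k <- value else drive[[param_name]] <- value
  list(params = params, drive = drive)
}

strobe_values <- function(traj, drive) {
  f <- if (drive$f1 > 0) drive$f1 else drive$f2
  if (f <= 0) stop("stroboscopic sampling needs a positive drive frequency")
  period <- 1 / f
  ts <- seq(traj$t[1], traj$t[length(traj$t)], by = period)
  idx <- findInterval(ts, traj$t)
  traj$states[idx, 1]
}

#' @export
print.hr_bifurcation <- function(x, ...) {
  cat("<hr_bifurcation>  parameter", x$param_name, "over [",
      min(x$grid), ",", max(x$grid), "],", length(x$grid), "points,",
      length(x$branches), "branch(es)\n")
  invisible(x)
}

#' Coexistence of attractors along a parameter grid
#'
#' Applies [detect_coexistence()] to a pair of initial conditions at
#' every grid point of the swept parameter.
#'
#' @inheritParams bifurcation_sweep
#' @param ic_pair List of exactly two initial conditions.
#' @param ... Passed to [detect_coexistence()].
#' @return Data frame with `param_value`, `coexists`, `distance`
#'   (failures propagate as `NA`).
#' @export
coexistence_region <- function(param_name, grid, ic_pair,
                               params = hr_params(), drive, ...) {
  param_name <- match.arg(param_name, c("A1", "f1", "f2", "k"))
  stopifnot(is.list(ic_pair), length(ic_pair) == 2L)
  rows <- lapply(grid, function(v) {
    pd <- set_swept(params, drive, param_name, v)
    res <- tryCatch(detect_coexistence(pd$params, pd$drive, ic_pair, ...),
                    error = function(e) NULL)
    data.frame(param_value = v,
               coexists = if (is.null(res)) NA else res$coexists,
               distance = if (is.null(res)) NA_real_ else res$distance)
  })
  do.call(rbind, rows)
}
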
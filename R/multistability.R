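#' Attractor fingerprint of a trajectory
#'
#' Deterministic summary used to decide whether two runs ended on the
#' same attractor: leading Lyapunov exponent (optional), mean and
#' standard deviation of `x`, a normalized ISI histogram on a fixed
#' binning, and the set of peak-amplitude clusters.
#'
#' @param traj Post-transient `hr_trajectory` of at least
#'   `min_duration` time units.
#' @param le1 Optional leading Lyapunov exponent.
#' @param isi_breaks Fixed histogram binning for the ISIs (an overflow
#'   bin is appended).
#' @param min_duration Minimum trajectory duration (default 100).
#' @param ... Passed to [detect_spikes()].
#' @return Object of class `hr_fingerprint`.
#' @export
attractor_fingerprint <- function(traj, le1 = NULL,
                                  isi_breaks = seq(0, 30, by = 0.5),
                                  min_duration = 100, ...) {
  stopifnot(inherits(traj, "hr_trajectory"))
  duration <- traj$t[length(traj$t)] - traj$t[1]
  if (duration < min_duration)
    stop("trajectory too short for a fingerprint (", duration, " < ",
         min_duration, " time units)")
  x <- traj$states[, 1]
  train <- detect_spikes(traj, ...)
  breaks <- c(isi_breaks, Inf)
  counts <- if (length(train$isi) > 0)
    tabulate(findInterval(train$isi, breaks, left.open = TRUE,
                          rightmost.closed = TRUE),
             nbins = length(breaks) - 1L)
  else rep(0L, length(breaks) - 1L)
  hist_norm <- if (sum(counts) > 0) counts / sum(counts) else counts
  structure(list(le1 = le1, mean_x = mean(x), sd_x = stats::sd(x),
                 isi_hist = hist_norm, n_spikes = length(train$times),
                 rate = length(train$times) / duration,
                 peak_clusters = cluster_count(train$peaks, 1e-2),
                 duration = duration),
            class = "hr_fingerprint")
}

#' Distance between two attractor fingerprints
#'
#' Weighted sum of the absolute difference in leading exponent (term
#' dropped when either is missing), absolute differences in mean and
#' standard deviation of `x`, the total-variation (L1/2) distance
#' between the normalized ISI histograms, and the relative spike-rate
#' difference (which separates quiescent stretches from firing ones —
#' the spike-conditional histogram alone cannot).
#'
#' @param f1,f2 `hr_fingerprint` objects.
#' @param weights Named weights `le1`, `mean`, `sd`, `hist`, `rate`.
#' @return Non-negative numeric distance.
#' @export
fingerprint_distance <- function(f1, f2,
                                 weights = c(le1 = 1, mean = 1,
                                             sd = 0.5, hist = 1,
                                             rate = 1)) {
  d <- weights[["mean"]] * abs(f1$mean_x - f2$mean_x) +
    weights[["sd"]] * abs(f1$sd_x - f2$sd_x) +
    weights[["hist"]] * sum(abs(f1$isi_hist - f2$isi_hist)) / 2 +
    weights[["rate"]] * abs(f1$rate - f2$rate) /
      (0.5 * (f1$rate + f2$rate) + 0.01)
  if (!is.null(f1$le1) && !is.null(f2$le1))
    d <- d + weights[["le1"]] * abs(f1$le1 - f2$le1)
  unname(d)
}

#' @export
print.hr_fingerprint <- function(x, ...) {
  cat("<hr_fingerprint>  mean_x =", format(x$mean_x, digits = 4),
      " sd_x =", format(x$sd_x, digits = 4),
      " spikes =", x$n_spikes)
  if (!is.null(x$le1)) cat("  LE1 =", format(x$le1, digits = 3))
  cat("\n")
  invisible(x)
}

# shared worker: integrate, keep final `keep_frac`, fingerprint
run_fingerprint <- function(params, drive, ic, t_end, keep_frac = 0.5,
                            compute_le = TRUE, le_horizon = 1000,
                            rtol = 1e-8, atol = 1e-10, sample_dt = 0.01) {
  traj <- hr_integrate(params, drive, ic, t_span = c(0, t_end),
                       rtol = rtol, atol = atol, sample_dt = sample_dt)
  tail_traj <- discard_transient(traj, (1 - keep_frac) * t_end)
  le1 <- if (compute_le)
    suppressWarnings(
      lyapunov_spectrum(params, drive, ic,
                        t_transient = (1 - keep_frac) * t_end,
                        t_horizon = le_horizon, rtol = rtol,
                        atol = atol)$exponents[1])
  else NULL
  list(traj = traj, tail = tail_traj,
       fingerprint = attractor_fingerprint(tail_traj, le1 = le1))
}

#' Detect coexisting attractors from a pair of initial conditions
#'
#' Runs the model from two initial conditions, fingerprints the final
#' `keep_frac` of each run, and reports coexistence when the
#' fingerprints differ by more than `tol`.  Symmetric in the pair.
#'
#' @param params,drive Model inputs.
#' @param ic_pair List of two initial conditions.
#' @param t_end Integration horizon (default 2000).
#' @param tol Distance tolerance for "same attractor" (default 0.35;
#'   same-attractor window pairs of a chaotic run score around 0.1-0.2,
#'   distinct attractors well above 1).
#' @param keep_frac Final fraction of each run used (default 0.5).
#' @param compute_le Include LE1 in the fingerprints (default TRUE).
#' @param le_horizon Averaging horizon for those exponents.
#' @param ... Tolerances passed to the integrator.
#' @return List: `coexists` (logical), `distance`, `fingerprints` (list
#'   of two), `tol`.
#' @export
detect_coexistence <- function(params, drive, ic_pair, t_end = 2000,
                               tol = 0.35, keep_frac = 0.5,
                               compute_le = TRUE, le_horizon = 1000, ...) {
  stopifnot(is.list(ic_pair), length(ic_pair) == 2L)
  runs <- lapply(ic_pair, function(ic)
    run_fingerprint(params, drive, ic, t_end, keep_frac,
                    compute_le, le_horizon, ...))
  d <- fingerprint_distance(runs[[1]]$fingerprint, runs[[2]]$fingerprint)
  list(coexists = d > tol, distance = d,
       fingerprints = lapply(runs, `[[`, "fingerprint"), tol = tol)
}

# windowed fingerprints of a trajectory: starts every `step`, width
# `window`; le1-free
window_fingerprints <- function(traj, window, step) {
  t0 <- traj$t[1]
  t1 <- traj$t[length(traj$t)]
  starts <- seq(t0, t1 - window, by = step)
  fps <- lapply(starts, function(s) {
    keep <- traj$t >= s & traj$t <= s + window
    attractor_fingerprint(
      as_hr_trajectory(traj$t[keep], traj$states[keep, , drop = FALSE]),
      min_duration = window * 0.9)
  })
  list(starts = starts, fps = fps)
}

#' Time of convergence onto the shared attractor
#'
#' For a parameter regime in which multistability is eliminated, the
#' trajectory from the second initial condition leaves its transient
#' orbit and merges into the attractor reached from the first.  A
#' window of `window` time units slides over the second run (kept from
#' `t = 0`); the convergence time is the earliest window start whose
#' fingerprint matches the first run's asymptotic fingerprint and stays
#' matched for every later window.  Matching uses hysteresis: the entry
#' tolerance is calibrated from the first run itself (the 95th
#' percentile of its own windowed self-distances, i.e. a window must be
#' statistically indistinguishable from an attractor window), while
#' "staying matched" only requires later windows to remain below
#' `stay_mult` times that tolerance, so ordinary chaotic
#' window-to-window variability does not postpone the detection.
#'
#' @param params,drive Model inputs.
#' @param ic_pair List of two initial conditions; the first defines the
#'   reference attractor.
#' @param window Window width (default 50 time units).
#' @param step Window stride (default 5).
#' @param t_end Horizon for the second run (default 600).
#' @param t_ref_end Horizon for the reference run (default 2000).
#' @param tol Optional fixed entry tolerance overriding the
#'   calibration.
#' @param stay_mult Persistence tolerance as a multiple of the entry
#'   tolerance (default 2).
#' @param ... Integrator tolerances.
#' @return The convergence time, or `NA` when the second run never
#'   merges (attributes `tol` and `distances` carry diagnostics).
#' @export
convergence_time <- function(params, drive, ic_pair, window = 50,
                             step = 5, t_end = 600, t_ref_end = 2000,
                             tol = NULL, stay_mult = 2, ...) {
  stopifnot(is.list(ic_pair), length(ic_pair) == 2L)
  ref_run <- hr_integrate(params, drive, ic_pair[[1]],
                          t_span = c(0, t_ref_end), ...)
  ref_tail <- discard_transient(ref_run, t_ref_end / 2)
  ref_fp <- attractor_fingerprint(ref_tail)
  if (is.null(tol)) {
    selfw <- window_fingerprints(ref_tail, window, step)
    self_d <- vapply(selfw$fps, fingerprint_distance, numeric(1), f2 = ref_fp)
    tol <- stats::quantile(self_d, 0.95, names = FALSE)
  }
  run2 <- hr_integrate(params, drive, ic_pair[[2]], t_span = c(0, t_end), ...)
  w <- window_fingerprints(run2, window, step)
  d <- vapply(w$fps, fingerprint_distance, numeric(1), f2 = ref_fp)
  # earliest entry (d < tol) after the last clear mismatch
  # (d > stay_mult * tol)
  last_bad <- rev(which(d > stay_mult * tol))[1]
  cand <- which(d < tol)
  if (!is.na(last_bad)) cand <- cand[cand > last_bad]
  t_conv <- if (length(cand)) w$starts[cand[1]] else NA_real_
  structure(t_conv, tol = tol,
            distances = data.frame(t = w$starts, distance = d))
}

#' Coupling-strength threshold for multistability elimination
#'
#' Sweeps the memristor coupling `k` over a grid spanning the
#' transition, tests [detect_coexistence()] at each point, and returns
#' the largest grid `k` at which the two runs have merged, refined by
#' one bisection level (half a grid step).  Chaotic transients make the
#' boundary fuzzy, so no high-precision root find is attempted.
#'
#' @param k_grid Increasing grid of coupling strengths (default
#'   `seq(-8, -6, by = 0.1)`).
#' @param params,drive Model inputs (`params$k` is overridden).
#' @param ic_pair List of two initial conditions.
#' @param ... Passed to [detect_coexistence()] (`t_end`, `tol`, ...).
#' @return List: `threshold` (largest merged `k`, `NA` when coexistence
#'   persists on the whole grid), `k_grid`, `coexists` (logical vector),
#'   `monotone` (TRUE when elimination is contiguous from the low end).
#' @export
elimination_threshold <- function(k_grid = seq(-8, -6, by = 0.1),
                                  params = hr_params(), drive, ic_pair,
                                  ...) {
  stopifnot(all(diff(k_grid) > 0))
  coexists <- vapply(k_grid, function(k) {
    p <- params; p$k <- k
    detect_coexistence(p, drive, ic_pair, ...)$coexists
  }, logical(1))
  if (all(coexists))
    return(list(threshold = NA_real_, k_grid = k_grid,
                coexists = coexists, monotone = NA))
  thr <- max(k_grid[!coexists])
  step <- stats::median(diff(k_grid))
  k_half <- thr + step / 2
  if (k_half < max(k_grid)) {
    p <- params; p$k <- k_half
    if (!detect_coexistence(p, drive, ic_pair, ...)$coexists)
      thr <- k_half
  }
  monotone <- !any(coexists[k_grid < thr])
  list(threshold = thr, k_grid = k_grid, coexists = coexists,
       monotone = monotone)
}
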
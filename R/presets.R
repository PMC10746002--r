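#' Preset registry of standard analysis scenarios
#'
#' Named parameter/drive/initial-condition bundles for the model's
#' benchmark scenarios: equilibrium tracking over one forcing period,
#' amplitude and frequency bifurcation sweeps, the three
#' coexisting-firing amplitudes, the two multistability-elimination
#' coupling strengths, the four low-frequency firing-pattern cases, and
#' the analog-circuit realization.  Each preset records the analysis
#' kind its name refers to plus the defaults (`t_end`, `transient`)
#' used by [run_report()].
#'
#' @return Named list of presets (class `hr_preset` each).
#' @examples
#' names(list_presets())
#' list_presets()[["table2_f2_0.07"]]
#' @export
list_presets <- function() {
  p1 <- hr_params(k = 1)
  mk <- function(name, kind, params, drive, ics, t_end, transient, note,
                 extra = list()) {
    structure(c(list(name = name, kind = kind, params = params,
                     drive = drive, ics = ics, t_end = t_end,
                     transient = transient, note = note), extra),
              class = "hr_preset")
  }
  single <- function(A1, f1 = 0.5) hr_drive(A1 = A1, f1 = f1)
  dual <- function(f2) hr_drive(A1 = 3, f1 = 0.5, A2 = 3, f2 = f2)
  ic_pair <- list(c(-5, 0, 0), c(5, 0, 0))
  presets <- list(
    mk("table1_equilibria", "equilibria", p1,
       hr_drive(A1 = 1, f1 = 0.05, A2 = 1, f2 = 0.05),
       list(c(1, -4, 1)), t_end = 25, transient = 0,
       "instantaneous equilibria and stability over one forcing period t in (5, 25)"),
    mk("fig2_A1_sweep", "sweep", p1, single(0.5), ic_pair,
       t_end = 500, transient = 250,
       "A1 bifurcation sweep over (0, 8) at k = 1, f1 = 0.5, paired initial conditions",
       list(sweep_param = "A1", sweep_range = c(0.1, 7.9))),
    mk("fig3_A1_0.1", "coexistence", p1, single(0.1), ic_pair,
       t_end = 2000, transient = 1000,
       "fixed point coexisting with chaotic spiking at A1 = 0.1"),
    mk("fig3_A1_3", "coexistence", p1, single(3), ic_pair,
       t_end = 2000, transient = 1000,
       "chaotic multi-spike bursting coexisting with a periodic limit cycle at A1 = 3"),
    mk("fig3_A1_5.5", "coexistence", p1, single(5.5), ic_pair,
       t_end = 2000, transient = 1000,
       "periodic spiking coexisting with a periodic limit cycle at A1 = 5.5"),
    mk("fig4_f1_sweep_low", "sweep", p1, single(3), list(c(-5, 0, 0)),
       t_end = 1500, transient = 750,
       "f1 bifurcation sweep over (0.01, 0.1) at A1 = 3",
       list(sweep_param = "f1", sweep_range = c(0.012, 0.098))),
    mk("fig5_f1_sweep_high", "sweep", p1, single(3), ic_pair,
       t_end = 500, transient = 250,
       "f1 bifurcation sweep over (0.1, 1) at A1 = 3, paired initial conditions",
       list(sweep_param = "f1", sweep_range = c(0.11, 0.99))),
    mk("fig6_k_minus7", "elimination", hr_params(k = -7), single(3), ic_pair,
       t_end = 2000, transient = 1000,
       "multistability elimination at k = -7, A1 = 3: merging near t = 270"),
    mk("fig7_k_minus10", "elimination", hr_params(k = -10), single(0.1),
       ic_pair, t_end = 2000, transient = 1000,
       "multistability elimination at k = -10, A1 = 0.1: merging near t = 200"),
    mk("table2_f2_0.002", "spectrum", p1, dual(0.002), list(c(-5, 0, 0)),
       t_end = 2000, transient = 500,
       "periodic bursting with irregular intra-burst spiking at f2 = 0.002"),
    mk("table2_f2_0.02", "spectrum", p1, dual(0.02), list(c(-5, 0, 0)),
       t_end = 2000, transient = 500,
       "periodic bursting with three spikes per burst at f2 = 0.02"),
    mk("table2_f2_0.04", "spectrum", p1, dual(0.04), list(c(-5, 0, 0)),
       t_end = 2000, transient = 500,
       "period-2 spiking at f2 = 0.04"),
    mk("table2_f2_0.07", "spectrum", p1, dual(0.07), list(c(-5, 0, 0)),
       t_end = 2000, transient = 500,
       "chaotic spiking at f2 = 0.07"),
    mk("table3_circuit", "circuit", p1, single(3), list(c(-5, 0, 0)),
       t_end = 0, transient = 0,
       "analog-circuit component values for the canonical parameters"))
  names(presets) <- vapply(presets, `[[`, character(1), "name")
  presets
}

#' @export
print.hr_preset <- function(x, ...) {
  cat("<hr_preset> ", x$name, " (", x$kind, ")\n  ", x$note, "\n", sep = "")
  invisible(x)
}

#' Fetch one preset by name
#'
#' @param name Preset name; unknown names raise an error listing the
#'   registry.
#' @return The `hr_preset`.
#' @export
get_preset <- function(name) {
  reg <- list_presets()
  if (!name %in% names(reg))
    stop("unknown preset '", name, "'; available: ",
         paste(names(reg), collapse = ", "))
  reg[[name]]
}

#' Run the full analysis chain of a preset
#'
#' Executes the analysis the preset stands for — equilibrium track,
#' bifurcation sweep, coexistence detection, elimination/convergence
#' analysis, Lyapunov spectrum plus firing classification, or circuit
#' mapping — and returns one JSON-serializable report.  Deterministic:
#' repeated calls give identical reports.
#'
#' @param name Preset name (see [list_presets()]).
#' @param t_end Optional override of the preset's horizon (e.g. for
#'   quick smoke runs).
#' @param le_horizon Lyapunov averaging horizon used where spectra are
#'   part of the chain (default 3000 for spectrum presets, 1000
#'   otherwise).
#' @param sweep_points Grid size for sweep presets (default 40).
#' @param ... Integrator tolerances passed through.
#' @return A named list (the report); serialize with
#'   `jsonlite::toJSON(..., auto_unbox = TRUE, digits = NA)`.
#' @export
run_report <- function(name, t_end = NULL, le_horizon = NULL,
                       sweep_points = 40, ...) {
  pr <- get_preset(name)
  t_end <- t_end %||% pr$t_end
  report <- list(preset = pr$name, kind = pr$kind, note = pr$note,
                 params = unclass(pr$params), drive = unclass(pr$drive))
  if (pr$kind == "circuit") {
    circ <- map_to_circuit(pr$params)
    report$circuit <- as.list(unclass(circ))
    report$frequency_map_Hz <- as.list(
      stats::setNames(scale_frequency(c(0.5, 0.002, 0.02, 0.04, 0.07)),
                      c("f_0.5", "f_0.002", "f_0.02", "f_0.04", "f_0.07")))
    return(report)
  }
  if (pr$kind == "equilibria") {
    tr <- equilibrium_track(pr$params, pr$drive,
                            t_grid = seq(5, 25, by = 0.05))
    iv <- stability_intervals(tr)
    report$stability_intervals <- iv
    report$n_times <- length(unique(tr$t))
    return(report)
  }
  if (pr$kind == "sweep") {
    grid <- seq(pr$sweep_range[1], pr$sweep_range[2],
                length.out = sweep_points)
    sw <- bifurcation_sweep(pr$sweep_param, grid, pr$ics,
                            params = pr$params, drive = pr$drive,
                            t_end = min(t_end, 500),
                            transient = min(pr$transient, 250),
                            le_horizon = le_horizon %||% 500, ...)
    report$sweep <- list(
      param = sw$param_name, grid = grid,
      le1 = lapply(sw$branches, `[[`, "le1"),
      n_peaks = lapply(sw$branches, function(b) {
        as.integer(table(factor(b$samples$param_value, levels = grid)))
      }))
    return(report)
  }
  if (pr$kind %in% c("coexistence", "elimination")) {
    cx <- detect_coexistence(pr$params, pr$drive, pr$ics, t_end = t_end,
                             le_horizon = le_horizon %||% 1000, ...)
    report$coexists <- cx$coexists
    report$distance <- cx$distance
    report$fingerprints <- lapply(cx$fingerprints, unclass)
    if (pr$kind == "elimination" && !cx$coexists && t_end >= 600) {
      tc <- convergence_time(pr$params, pr$drive, pr$ics,
                             t_end = min(t_end, 600),
                             t_ref_end = t_end, ...)
      report$convergence_time <- as.numeric(tc)
    }
    return(report)
  }
  # spectrum presets: LE spectrum + firing classification
  spec <- suppressWarnings(
    lyapunov_spectrum(pr$params, pr$drive, pr$ics[[1]],
                      t_transient = max(pr$transient, 500),
                      t_horizon = le_horizon %||% 3000, ...))
  traj <- hr_integrate(pr$params, pr$drive, pr$ics[[1]],
                       t_span = c(0, t_end), ...)
  pat <- classify_firing(discard_transient(traj, pr$transient),
                         le1 = spec$exponents[1])
  report$lyapunov <- list(exponents = spec$exponents,
                          horizon = spec$horizon,
                          converged = spec$converged)
  report$pattern <- unclass(pat)
  report
}
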
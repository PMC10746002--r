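#' Map model parameters to analog-circuit component values
#'
#' The analog realization integrates each state equation with an
#' inverting op-amp integrator (time constant `RC`, time-scaling factor
#' `tau0 = 1/(RC)`) and forms products with multipliers of gain 0.1 —
#' the origin of the factors of 10 in the coefficient identities.
#' Matching coefficients of the scaled circuit equations with the model
#' gives, with the anchor choices `R7`, `R11`, `R14`, `R15` and `C`:
#' \deqn{a = R_7/(10 R_1),\; b = R_7/(100 R_3),\; k = R_7/(10 R_4),}
#' \deqn{c = R_{11}/R_9,\; d = R_{11}/(10 R_8),\; \beta = R_o/(10 R_{15})}
#' with unit gains `R2 = R5 = R6 = R7`, `R10 = R11`, `R12 = R13 = R14`,
#' and the base resistance `R = 1/(tau0 C)`.  All resistances are in
#' kOhm, `C` in nF; values are exact rationals of the anchors (no
#' E-series rounding).
#'
#' @param params An [hr_params()] object; `alpha` must be 0 (the
#'   memductance block realizes the pure quadratic) and `a, b, c, d, k,
#'   beta` must be positive for realizability.
#' @param anchors Named list of fixed choices: `R7` (default 300), `R11`
#'   (100), `R14` (100), `R15` (100) in kOhm, `C` (50) in nF, `tau0`
#'   (10000) in 1/s.
#' @return Object of class `hr_circuit`: all resistances `R`, `R1..R15`,
#'   `Ro` (kOhm), `C` (nF), `tau0` (1/s).
#' @examples
#' map_to_circuit(hr_params())   # R = 2, R1 = 10, R3 = 3, R4 = 30 kOhm ...
#' @export
map_to_circuit <- function(params = hr_params(),
                           anchors = list(R7 = 300, R11 = 100, R14 = 100,
                                          R15 = 100, C = 50, tau0 = 1e4)) {
  if (params$alpha != 0)
    stop("the memductance block realizes W(phi) = beta*phi^2; alpha must be 0")
  solved <- list(
    R = 1e6 / (anchors$tau0 * anchors$C),         # kOhm
    R1 = anchors$R7 / (10 * params$a),
    R2 = anchors$R7,
    R3 = anchors$R7 / (100 * params$b),
    R4 = anchors$R7 / (10 * params$k),
    R5 = anchors$R7,
    R6 = anchors$R7,
    R7 = anchors$R7,
    R8 = anchors$R11 / (10 * params$d),
    R9 = anchors$R11 / params$c,
    R10 = anchors$R11,
    R11 = anchors$R11,
    R12 = anchors$R14,
    R13 = anchors$R14,
    R14 = anchors$R14,
    R15 = anchors$R15,
    Ro = 10 * params$beta * anchors$R15,
    C = anchors$C,
    tau0 = anchors$tau0)
  comp <- unlist(solved[setdiff(names(solved), "tau0")])
  if (any(!is.finite(comp)) || any(comp <= 0))
    stop("parameter set not realizable with these anchors: ",
         "a non-positive component value was solved (",
         paste(names(comp)[!is.finite(comp) | comp <= 0], collapse = ", "),
         ")")
  structure(solved, class = "hr_circuit")
}

#' @export
print.hr_circuit <- function(x, ...) {
  print(circuit_table(x))
  invisible(x)
}

#' Component table of a circuit realization
#'
#' @param circ An `hr_circuit` object.
#' @return Data frame with columns `name`, `role`, `value`, `unit`.
#' @export
circuit_table <- function(circ) {
  rnames <- c("R", paste0("R", 1:15), "Ro")
  data.frame(
    name = c(rnames, "C"),
    role = c(rep("resistance", length(rnames)), "capacitor"),
    value = c(unlist(circ[rnames]), circ$C),
    unit = c(rep("kOhm", length(rnames)), "nF"),
    row.names = NULL)
}

#' Recover model parameters from circuit components
#'
#' Inverts every coefficient identity of [map_to_circuit()].
#'
#' @param circ An `hr_circuit` object (or named list with the same
#'   fields).
#' @return An [hr_params()] object (with `alpha = 0`).
#' @export
circuit_to_params <- function(circ) {
  comp <- unlist(circ[c("R", paste0("R", 1:15), "Ro", "C")])
  if (any(!is.finite(comp)) || any(comp <= 0))
    stop("all component values must be positive and finite")
  hr_params(a = circ$R7 / (10 * circ$R1),
            b = circ$R7 / (100 * circ$R3),
            c = circ$R11 / circ$R9,
            d = circ$R11 / (10 * circ$R8),
            k = circ$R7 / (10 * circ$R4),
            alpha = 0,
            beta = circ$Ro / (10 * circ$R15))
}

#' Convert a dimensionless frequency to a physical circuit frequency
#'
#' @param f_dimensionless Dimensionless drive frequency.
#' @param tau0 Time-scaling factor in 1/s (default 10000).
#' @return Frequency in Hz: `f * tau0`.
#' @examples
#' scale_frequency(0.5)      # 5000 Hz
#' scale_frequency(0.002)    # 20 Hz
#' @export
scale_frequency <- function(f_dimensionless, tau0 = 1e4) {
  stopifnot(tau0 > 0)
  f_dimensionless * tau0
}
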
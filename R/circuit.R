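# The extracellular equivalent circuit: a purely resistive two-loop
# network linking the field source, the dendrite and soma nodes, and
# ground. Extracellular capacitance is neglected (quasi-static regime), so
# the network is solved algebraically at every instant.

#' Extracellular/intracellular resistance ratio from potassium
#'
#' Elevated extracellular potassium shrinks the extracellular volume
#' fraction and so raises the effective extracellular resistance. The model
#' captures this with a linear map from `[K+]o` to the ratio
#' `RDSout/RDSin = 0.1 + ([K+]o - 3.5) * 0.01`, so physiological
#' 3.5 mM gives ratio 0.1 and elevated 8.5 mM gives 0.15.
#'
#' @param Ko Extracellular potassium concentration (mM, >= 0).
#' @return Dimensionless positive ratio.
#' @examples
#' resistance_ratio_from_potassium(c(3.5, 6.0, 8.5))
#' @export
resistance_ratio_from_potassium <- function(Ko) {
  if (any(!is.finite(Ko)) || any(Ko < 0)) stop("Ko must be finite and non-negative")
  r <- 0.1 + (Ko - 3.5) * 0.01
  if (any(r <= 0)) stop("nonphysical resistance ratio: r must be positive")
  r
}

#' Intracellular dendro-somatic resistance from the coupling conductance
#'
#' `RDSin = 1 / (gc * area)`: the reciprocal of the inter-compartment
#' coupling conductance density times total membrane area, converted to
#' megaohms (gc in mS/cm^2 and area in cm^2 give 1/mS = kOhm). The default
#' parameters (gc = 2.1 mS/cm^2, area = 6e-6 cm^2) give about 79.4 MOhm,
#' conventionally quoted as ~80 MOhm.
#'
#' @param gc Coupling conductance (mS/cm^2, > 0).
#' @param area Total membrane area (cm^2, > 0).
#' @return Resistance in MOhm.
#' @examples
#' intracellular_resistance(2.1, 6e-6)  # ~79.37
#' @export
intracellular_resistance <- function(gc, area) {
  if (any(gc <= 0) || any(area <= 0)) stop("gc and area must be positive")
  1 / (gc * area) / 1000
}

#' Extracellular circuit parameters
#'
#' Builds the resistive network around the neuron: the intracellular
#' dendro-somatic resistance `RDSin`, the extracellular dendrite-soma
#' resistance `RDSout = r * RDSin`, and the access resistances between the
#' field terminal and the dendrite node (`RTD`) and between the soma node
#' and ground (`RSG`). Specify the extracellular side either directly
#' through `Rout` (MOhm; `r` is then back-computed for reporting), through
#' the ratio `r`, or through the extracellular potassium concentration
#' `Ko` (mM) via [resistance_ratio_from_potassium()].
#'
#' The access resistances are tied to one of the dendro-somatic
#' resistances, `RTD = RSG = RDSin / 2` (`terminals = "intracellular"`,
#' the default) or `RTD = RSG = RDSout / 2` (`terminals =
#' "extracellular"`). The choice controls how the field transfer scales
#' with `Rout`: with the intracellular tie the source-loop resistance is
#' dominated by the fixed `RDSin`, so the voltage appearing across
#' `RDSout` grows essentially linearly with `Rout`
#' (`VDSout ~ Ve * Rout / (RDSin + 2 Rout)`) and the neuron's field
#' sensitivity increases with extracellular resistance -- the regime this
#' model is built to study. With the extracellular tie the transfer
#' `RDSin / (2 RDSin + Rout)` is nearly independent of `Rout` (and slightly
#' decreasing), which suppresses the Rout sensitivity entirely; it is kept
#' as an explicit option for comparison. See the package vignette for the
#' full rationale.
#'
#' @param RDSin Intracellular dendro-somatic resistance (MOhm). Defaults to
#'   [intracellular_resistance()] of the standard gc and area.
#' @param Rout Extracellular dendrite-soma resistance (MOhm), or `NULL`.
#' @param r Dimensionless extracellular/intracellular ratio, or `NULL`.
#' @param Ko Extracellular potassium (mM), or `NULL`. Exactly one of
#'   `Rout`, `r`, `Ko` is used; default is ratio 0.1.
#' @param terminals Tie for the access resistances: `"intracellular"`
#'   (`RTD = RSG = RDSin/2`) or `"extracellular"` (`RTD = RSG = RDSout/2`).
#' @param RTD,RSG Explicit access resistances (MOhm); override `terminals`
#'   when given (both required together).
#' @return Object of class `circuit_parameters` with fields `RDSin`, `r`,
#'   `RDSout`, `RTD`, `RSG` (MOhm).
#' @examples
#' circuit_parameters(Rout = 10)
#' circuit_parameters(Ko = 8.5, terminals = "extracellular")
#' @export
circuit_parameters <- function(RDSin = intracellular_resistance(2.1, 6e-6),
                               Rout = NULL, r = NULL, Ko = NULL,
                               terminals = c("intracellular", "extracellular"),
                               RTD = NULL, RSG = NULL) {
  terminals <- match.arg(terminals)
  if (RDSin <= 0) stop("RDSin must be positive")
  given <- c(!is.null(Rout), !is.null(r), !is.null(Ko))
  if (sum(given) > 1L) stop("give at most one of `Rout`, `r`, `Ko`")
  if (!is.null(Ko)) r <- resistance_ratio_from_potassium(Ko)
  if (!is.null(Rout)) {
    if (Rout <= 0) stop("Rout must be positive")
    r <- Rout / RDSin
  } else {
    if (is.null(r)) r <- 0.1
    if (r <= 0) stop("resistance ratio r must be positive")
    Rout <- r * RDSin
  }
  if (is.null(RTD) != is.null(RSG)) stop("give RTD and RSG together")
  if (is.null(RTD)) {
    RTD <- RSG <- if (terminals == "intracellular") RDSin / 2 else Rout / 2
  }
  if (RTD <= 0 || RSG <= 0) stop("access resistances must be positive")
  structure(list(RDSin = RDSin, r = r, RDSout = Rout, RTD = RTD, RSG = RSG),
            class = "circuit_parameters")
}

#' @export
print.circuit_parameters <- function(x, ...) {
  cat(sprintf(
    "Extracellular circuit: RDSin = %.3f MOhm, RDSout = %.3f MOhm (r = %.4f), RTD = RSG = %.3f MOhm\n",
    x$RDSin, x$RDSout, x$r, x$RTD))
  invisible(x)
}

#' Sinusoidal field stimulus
#'
#' The applied field enters the circuit as an AC voltage source
#' `Ve(t) = A * sin(2 * pi * f * t / 1000)` (t in ms, f in Hz) between the
#' field terminal and ground. Under the parallel-plate approximation the
#' source amplitude is `A = E0 * d`, the field intensity times the
#' effective soma-dendrite distance, so `A` is in mV.
#'
#' @param A Source amplitude (mV, >= 0). May be omitted when `E0` and `d`
#'   are both given.
#' @param f Field frequency (Hz, > 0).
#' @param E0 Field intensity (mV/mm), optional.
#' @param d Effective soma-dendrite distance (mm), optional.
#' @return Object of class `field_stimulus`.
#' @examples
#' field_stimulus(A = 100, f = 10)
#' field_stimulus(E0 = 20, d = 5, f = 40)  # A = 100 mV
#' @export
field_stimulus <- function(A = NULL, f, E0 = NULL, d = NULL) {
  if (!is.null(E0) || !is.null(d)) {
    if (is.null(E0) || is.null(d)) stop("E0 and d must be given together")
    if (is.null(A)) A <- E0 * d
    if (abs(A - E0 * d) > 1e-9 * max(1, abs(A))) {
      stop("inconsistent stimulus: A must equal E0 * d")
    }
  }
  if (is.null(A)) stop("stimulus amplitude A (or E0 and d) required")
  if (A < 0) stop("amplitude A must be non-negative")
  if (f <= 0) stop("field frequency f must be positive")
  structure(list(A = A, f = f, E0 = E0, d = d), class = "field_stimulus")
}

#' @export
print.field_stimulus <- function(x, ...) {
  cat(sprintf("Sinusoidal field stimulus: A = %g mV, f = %g Hz\n", x$A, x$f))
  invisible(x)
}

#' Instantaneous field source voltage
#'
#' @param stim A [field_stimulus()].
#' @param t Time (ms, >= 0); vectorized.
#' @return `Ve = A * sin(2 * pi * f * t / 1000)` in mV.
#' @examples
#' field_voltage(field_stimulus(A = 100, f = 10), c(0, 25, 50))
#' @export
field_voltage <- function(stim, t) {
  if (any(t < 0)) stop("t must be non-negative")
  stim$A * sin(2 * pi * stim$f * t / 1000)
}

#' Quasi-static Kirchhoff solution of the extracellular network
#'
#' Solves the two-loop Kirchhoff system of the extracellular circuit,
#' ```
#'   i1 * (RDSin + RDSout) + i2 * RDSout                = Vs - Vd
#'   i1 * RDSout           + i2 * (RTD + RSG + RDSout)  = Ve
#' ```
#' and returns the loop currents together with the voltage across the
#' extracellular dendrite-soma resistance, `VDSout = (i1 + i2) * RDSout`.
#' The generic linear solve is used here; the algebraically reduced form
#' (exposed in [vdsout_closed_form()], used at every derivative call inside
#' the simulator) must agree with it. With the extracellular terminal tie
#' `RTD = RSG = RDSout/2` the reduction is
#' `VDSout = (RDSout * (Vs - Vd) + RDSin * Ve) / (2 * RDSin + RDSout)`.
#'
#' @param circuit A [circuit_parameters()].
#' @param Vs,Vd Somatic and dendritic potentials (mV).
#' @param Ve Instantaneous field source voltage (mV).
#' @return List with loop currents `i1`, `i2` (nA) and `VDSout` (mV).
#' @examples
#' cp <- circuit_parameters(RDSin = 80, Rout = 8, terminals = "extracellular")
#' extracellular_voltage(cp, Vs = 0, Vd = 0, Ve = 168)$VDSout  # 80 mV
#' @export
extracellular_voltage <- function(circuit, Vs, Vd, Ve) {
  M <- matrix(c(circuit$RDSin + circuit$RDSout, circuit$RDSout,
                circuit$RDSout, circuit$RTD + circuit$RSG + circuit$RDSout),
              nrow = 2, byrow = TRUE)
  if (abs(det(M)) < .Machine$double.eps * max(abs(M))^2) {
    stop("singular extracellular network")
  }
  i <- solve(M, c(Vs - Vd, Ve))
  list(i1 = i[1], i2 = i[2], VDSout = (i[1] + i[2]) * circuit$RDSout)
}

#' Closed-form extracellular voltage
#'
#' Algebraic reduction of [extracellular_voltage()]'s two-loop solve, with
#' `S = RTD + RSG` the source-loop access resistance:
#' `VDSout = RDSout * (S * (Vs - Vd) + RDSin * Ve) /
#' ((RDSin + RDSout) * (S + RDSout) - RDSout^2)`.
#' Under the extracellular tie `S = RDSout` this simplifies to
#' `(RDSout * (Vs - Vd) + RDSin * Ve) / (2 * RDSin + RDSout)`; under the
#' intracellular tie `S = RDSin` to
#' `RDSout * ((Vs - Vd) + Ve) / (RDSin + 2 * RDSout)`. Vectorized over
#' `Vs`, `Vd`, `Ve`; this is the expression evaluated at every derivative
#' call inside the simulator.
#'
#' @inheritParams extracellular_voltage
#' @return `VDSout` in mV.
#' @export
vdsout_closed_form <- function(circuit, Vs, Vd, Ve) {
  S <- circuit$RTD + circuit$RSG
  circuit$RDSout * (S * (Vs - Vd) + circuit$RDSin * Ve) /
    ((circuit$RDSin + circuit$RDSout) * (S + circuit$RDSout) -
       circuit$RDSout^2)
}
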
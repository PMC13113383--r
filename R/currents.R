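# Membrane currents, calcium dynamics and synaptic-gate dynamics.

#' All membrane currents at a given state
#'
#' Evaluates every ionic, leak, synaptic and coupling current of the
#' two-compartment model at one state (uA/cm^2). Sodium activation is
#' instantaneous: `INa = gNa * m_inf(Vs)^2 * h * (Vs - VNa)`. The
#' inter-compartment current includes the extracellular contribution,
#' `IDSin = gc * (Vd + VDSout - Vs)`; with `VDSout = 0` this reduces to the
#' classical coupling current `gc * (Vd - Vs)`.
#'
#' @param state A [neuron_state()] (or named numeric with the same fields).
#' @param params A [neuron_parameters()].
#' @param VDSout Instantaneous voltage (mV) across the extracellular
#'   dendrite-soma resistance (see [extracellular_voltage()]); 0 for the
#'   uncoupled model.
#' @param synapse_mode `"self"` (the neuron's own somatic spikes drive the
#'   NMDA/AMPA gates) or `"off"` (`Isyn` identically 0).
#'
#' @return Named list of currents: `Isleak`, `Idleak`, `INa`, `IKDR`,
#'   `IKC`, `ICa`, `IKAHP`, `INMDA`, `IAMPA`, `Isyn`, `IDSin`, with
#'   `Isyn = INMDA + IAMPA` exactly.
#' @examples
#' st <- neuron_state(Vs = 5, Vd = -2, h = 0.9, n = 0.1, s = 0.05,
#'                    c = 0.2, q = 0.01, Ca = 50)
#' ionic_currents(st, neuron_parameters())$INa
#' @export
ionic_currents <- function(state, params, VDSout = 0,
                           synapse_mode = c("self", "off")) {
  synapse_mode <- match.arg(synapse_mode)
  s_ <- as.list(state)
  p <- params
  m_inf <- gate_steady_and_tau("m", s_$Vs)$inf
  INMDA <- p$gNMDA * s_$Si /
    (1 + 0.28 * exp(-0.062 * (s_$Vd - 60))) * (s_$Vd - p$Vsyn)
  IAMPA <- p$gAMPA * s_$Wi * (s_$Vd - p$Vsyn)
  if (synapse_mode == "off") INMDA <- IAMPA <- 0
  out <- list(
    Isleak = p$gL * (s_$Vs - p$VL),
    Idleak = p$gL * (s_$Vd - p$VL),
    INa    = p$gNa * m_inf^2 * s_$h * (s_$Vs - p$VNa),
    IKDR   = p$gKDR * s_$n * (s_$Vs - p$VK),
    IKC    = p$gKC * s_$c * chi(s_$Ca) * (s_$Vd - p$VK),
    ICa    = p$gCa * s_$s^2 * (s_$Vd - p$VCa),
    IKAHP  = p$gKAHP * s_$q * (s_$Vd - p$VK),
    INMDA  = INMDA,
    IAMPA  = IAMPA,
    Isyn   = INMDA + IAMPA,
    IDSin  = p$gc * (s_$Vd + VDSout - s_$Vs)
  )
  out
}

#' Calcium concentration derivative
#'
#' `dCa/dt = -0.13 * ICa - 0.075 * Ca`. In this model's sign convention the
#' calcium current is negative for inward flux, so an open calcium channel
#' raises `Ca` while the second term relaxes it back to zero.
#'
#' @param Ca Calcium concentration (>= 0).
#' @param ICa Calcium current (uA/cm^2).
#' @return `dCa/dt` (model units per ms).
#' @examples
#' calcium_derivative(Ca = 100, ICa = 0)   # -7.5
#' calcium_derivative(Ca = 0, ICa = -10)   # +1.3
#' @export
calcium_derivative <- function(Ca, ICa) {
  if (any(Ca < 0)) stop("Ca must be non-negative")
  -0.13 * ICa - 0.075 * Ca
}

#' Synaptic gate derivatives
#'
#' First-order dynamics of the NMDA (`Si`) and AMPA (`Wi`) gate weights,
#' driven by a Heaviside step on the presynaptic somatic potential:
#' `dSi/dt = H(Vs - 10) - Si/150`, `dWi/dt = H(Vs - 20) - Wi/2`, with
#' `H(x) = 1` for `x >= 0` and `0` otherwise. In the single-neuron model
#' the presynaptic sum collapses to the cell's own soma (`"self"` mode) or
#' is absent (`"off"`).
#'
#' @param Si,Wi Current gate weights (>= 0).
#' @param Vs_pre Presynaptic somatic potential (mV).
#' @param synapse_mode `"self"` or `"off"`.
#' @return List with `dSi` and `dWi` (1/ms).
#' @examples
#' synaptic_gate_derivatives(0, 0, Vs_pre = 30)  # dSi = dWi = 1
#' @export
synaptic_gate_derivatives <- function(Si, Wi, Vs_pre,
                                      synapse_mode = c("self", "off")) {
  synapse_mode <- match.arg(synapse_mode)
  if (any(Si < 0) || any(Wi < 0)) stop("synaptic gates must be non-negative")
  drive <- if (synapse_mode == "self") 1 else 0
  list(dSi = drive * as.numeric(Vs_pre >= 10) - Si / 150,
       dWi = drive * as.numeric(Vs_pre >= 20) - Wi / 2)
}
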
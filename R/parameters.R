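#' Neuron parameters for the two-compartment CA3 pyramidal cell
#'
#' Constructs the full parameter set of the two-compartment
#' (Pinsky-Rinzel-type) CA3 pyramidal neuron: compartment geometry, membrane
#' capacitance, channel conductances, reversal potentials and constant
#' injected currents. Defaults are the standard values for this model; the
#' dendritic drive `Id = 0.7` uA/cm^2 is the sole tonic input and by itself
#' produces repetitive firing.
#'
#' All reversal potentials are in the model voltage frame referenced to
#' -60 mV (rest near 0 mV); no conversion to absolute millivolts is applied
#' anywhere in the package.
#'
#' @param p Soma fraction of total membrane area, in (0, 1).
#' @param Cm Membrane capacitance (uF/cm^2).
#' @param gc Inter-compartment coupling conductance (mS/cm^2).
#' @param gL,gNa,gKDR,gCa,gKAHP,gKC,gNMDA,gAMPA Channel conductances
#'   (mS/cm^2).
#' @param VNa,VCa,VK,VL,Vsyn Reversal potentials (mV, model frame).
#' @param Is,Id Constant injected currents to soma and dendrite (uA/cm^2).
#' @param area Total membrane area (cm^2).
#'
#' @return An object of class `neuron_parameters` (named list).
#' @examples
#' np <- neuron_parameters()
#' np$VK
#' neuron_parameters(VK = -80)$VK
#' @export
neuron_parameters <- function(p = 0.5, Cm = 3.0, gc = 2.1,
                              gL = 0.1, gNa = 30, gKDR = 15, gCa = 10,
                              gKAHP = 0.8, gKC = 15,
                              gNMDA = 0.03, gAMPA = 0.0045,
                              VNa = 120, VCa = 140, VK = -38.56, VL = 0,
                              Vsyn = 60, Is = 0, Id = 0.7,
                              area = 6e-6) {
  out <- list(p = p, Cm = Cm, gc = gc,
              gL = gL, gNa = gNa, gKDR = gKDR, gCa = gCa,
              gKAHP = gKAHP, gKC = gKC, gNMDA = gNMDA, gAMPA = gAMPA,
              VNa = VNa, VCa = VCa, VK = VK, VL = VL, Vsyn = Vsyn,
              Is = Is, Id = Id, area = area)
  validate_neuron_parameters(out)
  structure(out, class = "neuron_parameters")
}

validate_neuron_parameters <- function(x) {
  stopifnot(is.numeric(x$p), length(x$p) == 1L)
  if (!(x$p > 0 && x$p < 1)) stop("soma area fraction `p` must lie in (0, 1)")
  if (!(x$Cm > 0)) stop("membrane capacitance `Cm` must be positive")
  if (!(x$area > 0)) stop("membrane `area` must be positive")
  g <- c(x$gc, x$gL, x$gNa, x$gKDR, x$gCa, x$gKAHP, x$gKC, x$gNMDA, x$gAMPA)
  if (any(!is.finite(g)) || any(g < 0)) {
    stop("all conductances must be finite and non-negative")
  }
  v <- c(x$VNa, x$VCa, x$VK, x$VL, x$Vsyn, x$Is, x$Id)
  if (any(!is.finite(v))) stop("reversal potentials and currents must be finite")
  invisible(x)
}

#' @export
print.neuron_parameters <- function(x, ...) {
  cat("Two-compartment CA3 neuron parameters (model frame, ref -60 mV)\n")
  cat(sprintf("  p = %g, Cm = %g uF/cm^2, gc = %g mS/cm^2, area = %g cm^2\n",
              x$p, x$Cm, x$gc, x$area))
  cat(sprintf("  g (mS/cm^2): L=%g Na=%g KDR=%g Ca=%g KAHP=%g KC=%g NMDA=%g AMPA=%g\n",
              x$gL, x$gNa, x$gKDR, x$gCa, x$gKAHP, x$gKC, x$gNMDA, x$gAMPA))
  cat(sprintf("  V (mV): Na=%g Ca=%g K=%g L=%g syn=%g;  I (uA/cm^2): Is=%g Id=%g\n",
              x$VNa, x$VCa, x$VK, x$VL, x$Vsyn, x$Is, x$Id))
  invisible(x)
}

#' Neuron state vector
#'
#' Bundles the full dynamical state of the model in its fixed ordering
#' `(Vs, Vd, h, n, s, c, q, Ca, Si, Wi)`: somatic and dendritic membrane
#' potentials (mV, model frame), the five Hodgkin-Huxley gating variables,
#' intracellular calcium (model units), and the NMDA (`Si`) and AMPA (`Wi`)
#' synaptic gate weights. The sodium activation gate `m` is instantaneous
#' (always at its steady state) and is not part of the state.
#'
#' @param Vs,Vd Compartment membrane potentials (mV).
#' @param h,n,s,c,q Gating variables, each in `[0, 1]`.
#' @param Ca Calcium concentration (model units, >= 0).
#' @param Si,Wi Synaptic gate weights (>= 0).
#'
#' @return A named numeric vector of class `neuron_state`.
#' @examples
#' st <- neuron_state(Vs = -3, Vd = -2, h = 0.99, n = 0.02, s = 0.01,
#'                    c = 0.1, q = 0.01, Ca = 0.2)
#' @export
neuron_state <- function(Vs = 0, Vd = 0, h = 0, n = 0, s = 0, c = 0, q = 0,
                         Ca = 0, Si = 0, Wi = 0) {
  x <- c(Vs = Vs, Vd = Vd, h = h, n = n, s = s, c = c, q = q,
         Ca = Ca, Si = Si, Wi = Wi)
  if (any(!is.finite(x))) stop("neuron state must be finite")
  if (any(x[c("h", "n", "s", "c", "q")] < 0) ||
      any(x[c("h", "n", "s", "c", "q")] > 1)) {
    stop("gating variables h, n, s, c, q must lie in [0, 1]")
  }
  if (x[["Ca"]] < 0) stop("calcium concentration must be non-negative")
  if (x[["Si"]] < 0 || x[["Wi"]] < 0) stop("synaptic gates must be non-negative")
  structure(x, class = c("neuron_state", "numeric"))
}

state_names <- c("Vs", "Vd", "h", "n", "s", "c", "q", "Ca", "Si", "Wi")
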
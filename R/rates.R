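# Gating-rate kinetics of the two-compartment CA3 model.
#
# Several rates have the form k*(a - V) / (exp((a - V)/b) - 1), which has a
# removable singularity at V = a with limit k*b. `vtrap()` evaluates that
# form through expm1 and a first-order series inside |x/b| < 1e-7, so the
# rates are continuous through the singular voltage.

vtrap <- function(k, x, b) {
  u <- x / b
  ifelse(abs(u) < 1e-7, k * b * (1 - u / 2), k * b * u / expm1(u))
}

#' Forward/backward rate constants for one gating variable
#'
#' Evaluates the voltage- (or calcium-) dependent transition rates
#' `alpha` and `beta` for a gating variable of the two-compartment CA3
#' model. Gates `m`, `h`, `n` depend on the somatic potential, `s` and `c`
#' on the dendritic potential, and the AHP gate `q` on calcium only
#' (`alpha_q = min(0.00002 * Ca, 0.01)`, `beta_q = 0.001`). Gate `c` is
#' piecewise in voltage with a split at `V = 50` mV; both branches join
#' continuously.
#'
#' Rates with a removable singularity (`alpha_m`, `beta_m`, `alpha_n`,
#' `beta_s`) are evaluated in a numerically stable form and take their
#' analytic limit at the singular voltage.
#'
#' @param gate One of `"m"`, `"h"`, `"n"`, `"s"`, `"c"`, `"q"`.
#' @param V Membrane potential (mV, model frame); vectorized.
#' @param Ca Calcium concentration (>= 0); used only by gate `"q"`.
#'
#' @return A list with numeric components `alpha` and `beta` (1/ms).
#' @examples
#' rate_constants("n", 35.1)$alpha   # analytic limit 0.016 * 5 = 0.08
#' rate_constants("q", 0, Ca = 500)  # alpha capped at 0.01
#' @export
rate_constants <- function(gate, V, Ca = 0) {
  if (!is.character(gate) || length(gate) != 1L ||
      !gate %in% c("m", "h", "n", "s", "c", "q")) {
    stop("invalid gate: must be one of 'm', 'h', 'n', 's', 'c', 'q'")
  }
  if (gate != "q" && any(!is.finite(V))) stop("V must be finite")
  if (gate == "q" && any(Ca < 0)) stop("Ca must be non-negative")
  switch(gate,
    m = list(alpha = vtrap(0.32, 13.1 - V, 4),
             beta  = vtrap(0.28, V - 40.1, 5)),
    h = list(alpha = 0.128 * exp((17 - V) / 18),
             beta  = 4 / (1 + exp((40 - V) / 5))),
    n = list(alpha = vtrap(0.016, 35.1 - V, 5),
             beta  = 0.25 * exp(0.5 - 0.025 * V)),
    s = list(alpha = 1.6 / (1 + exp(-0.072 * (V - 65))),
             beta  = vtrap(0.02, V - 51.1, 5)),
    c = {
      lo <- V <= 50
      a_lo <- exp((V - 10) / 11 - (V - 6.5) / 27) / 18.975
      a_hi <- 2 * exp((6.5 - V) / 27)
      alpha <- ifelse(lo, a_lo, a_hi)
      # a_hi - a_lo dips a few 1e-5 below zero just under the split in the
      # canonical forms; clamp so c stays a true gating variable in [0,1]
      beta <- pmax(ifelse(lo, a_hi - a_lo, 0), 0)
      list(alpha = alpha, beta = beta)
    },
    q = list(alpha = pmin(0.00002 * Ca, 0.01),
             beta  = rep_len(0.001, length(Ca)))
  )
}

#' Steady state and time constant of a gating variable
#'
#' First-order gate kinetics `dy/dt = (y_inf - y)/tau` with
#' `y_inf = alpha/(alpha + beta)` and `tau = 1/(alpha + beta)`.
#'
#' @inheritParams rate_constants
#' @return A list with components `inf` (dimensionless, in `[0, 1]`) and
#'   `tau` (ms, > 0).
#' @examples
#' gate_steady_and_tau("q", V = 0, Ca = 500)  # inf = 10/11, tau = 1/0.011
#' @export
gate_steady_and_tau <- function(gate, V, Ca = 0) {
  r <- rate_constants(gate, V, Ca)
  denom <- r$alpha + r$beta
  if (any(denom <= 0)) stop("degenerate kinetics: alpha + beta must be positive")
  list(inf = r$alpha / denom, tau = 1 / denom)
}

#' Calcium saturation factor of the fast calcium-activated K+ current
#'
#' `chi(Ca) = min(Ca / 250, 1)`: linear in calcium up to the cap at 1.
#' Multiplies the `c`-gated potassium conductance.
#'
#' @param Ca Calcium concentration (>= 0); vectorized.
#' @return Dimensionless factor in `[0, 1]`.
#' @examples
#' chi(c(0, 125, 1000))
#' @export
chi <- function(Ca) {
  if (any(!is.finite(Ca)) || any(Ca < 0)) stop("Ca must be finite and non-negative")
  pmin(Ca / 250, 1)
}
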
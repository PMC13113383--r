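---
title: "Modelling neuronal sensitivity to weak AC fields with an explicit extracellular resistance"
author: "prfield"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling neuronal sensitivity to weak AC fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prfield)
```

## The model

`prfield` simulates a reduced hippocampal CA3 pyramidal neuron — a
two-compartment (Pinsky–Rinzel-type) cell with a spiking soma and a
bursting dendrite — embedded in an explicit extracellular resistance
network and driven by a weak sinusoidal electric field, the configuration
used to study entrainment under transcranial alternating current
stimulation (tACS).

The soma carries the fast sodium and delayed-rectifier potassium currents,
the dendrite the calcium, calcium-activated potassium (fast `c`-gated and
slow AHP `q`-gated) and NMDA/AMPA synaptic currents. The cable equations
are

$$C_m \dot V_s = -I_{sLeak} - I_{Na} - I_{KDR} + \frac{I_{DSin}}{p} + \frac{I_s}{p},$$
$$C_m \dot V_d = -I_{dLeak} - I_{Ca} - I_{KAHP} - I_{KC} - I_{syn} - \frac{I_{DSin}}{1-p} + \frac{I_d}{1-p},$$

with $p = 0.5$ the somatic area fraction and all voltages in the model
frame referenced to $-60$ mV (rest near 0 mV). Gating variables follow
first-order kinetics $\dot y = \alpha_y (1-y) - \beta_y y$ with the
classical rate functions of this cell model; sodium activation is
instantaneous ($m = m_\infty(V_s)$). Calcium obeys
$\dot{Ca} = -0.13\,I_{Ca} - 0.075\,Ca$ and gates the `c` current through
$\chi(Ca) = \min(Ca/250, 1)$.

Two typographic defects of the commonly tabulated rate set are corrected
to the canonical forms: $\alpha_m = 0.32\,(13.1 - V_s)/(e^{(13.1-V_s)/4}-1)$
and $\beta_h = 4/(1 + e^{(40-V_s)/5})$. With the sign-flipped variants
sometimes seen in print, $m_\infty(0) \approx 0.28$ and
$h_\infty(0) \approx 0.08$, and the cell sits in permanent depolarization
block — it cannot fire under its standard dendritic drive
$I_d = 0.7\ \mu\mathrm{A/cm^2}$, contradicting every known firing regime
of this model. Rates of the form $k\,(a-V)/(e^{(a-V)/b}-1)$ are evaluated
through `expm1` with a series fallback inside $|V-a| < 4\times10^{-7}$ mV,
so they are continuous through their removable singularities
(e.g. $\alpha_n(35.1) = 0.08$ exactly in the limit). The tiny negative
excursion of $\beta_c$ just below the $V_d = 50$ branch point of the
canonical `c` forms (about $-4\times10^{-5}$) is clamped to zero so `c`
remains a true gating variable in $[0,1]$.

## The extracellular circuit

The field is applied as an AC voltage source $V_E(t) = A \sin(2\pi f t)$
(with $A = E_0 d$, field intensity times effective soma–dendrite
distance) across a purely resistive two-loop network: the source reaches
the dendrite node through an access resistance $R_{TD}$, the extracellular
dendrite–soma path carries $R_{DSout}$, the soma node drains to ground
through $R_{SG}$, and the intracellular dendro-somatic path carries
$R_{DSin} = 1/(g_c \cdot \mathrm{Area}) \approx 79.4\ \mathrm{M\Omega}$.
Extracellular capacitance is neglected (quasi-static regime), so Kirchhoff's
loop equations

$$i_1 (R_{DSin} + R_{DSout}) + i_2 R_{DSout} = V_s - V_d,\qquad
  i_1 R_{DSout} + i_2 (R_{TD} + R_{SG} + R_{DSout}) = V_E$$

are solved algebraically at every derivative evaluation, yielding
$V_{DSout} = (i_1 + i_2) R_{DSout}$, the extracellular voltage that enters
the coupling current $I_{DSin} = g_c (V_d + V_{DSout} - V_s)$.

Physiology enters through extracellular potassium: elevated
$[K^+]_o$ shrinks the extracellular volume fraction and raises the
resistance ratio $r = R_{DSout}/R_{DSin} = 0.1 + ([K^+]_o - 3.5)\times0.01$,
so $[K^+]_o \in [3.5, 8.5]$ mM maps onto
$R_{DSout} \in [\sim 8, \sim 12]\ \mathrm{M\Omega}$.

### The access-resistance tie (a genuinely open design point)

The two access resistances must be tied to something. Tying them to the
extracellular path, $R_{TD} = R_{SG} = R_{DSout}/2$, gives the field
transfer $V_{DSout}/V_E = R_{DSin}/(2R_{DSin} + R_{DSout}) \approx 0.47$ —
essentially independent of $R_{out}$ and slightly *decreasing* in it.
Under that tie the firing rate at 5 Hz / 100 mV is numerically flat
(16.5 Hz across $R_{out} = 8\ldots12\ \mathrm{M\Omega}$ in our
simulations) and the model has no extracellular-resistance sensitivity to
study. Tying them instead to the fixed intracellular resistance,
$R_{TD} = R_{SG} = R_{DSin}/2$, gives
$V_{DSout}/V_E = R_{out}/(R_{DSin} + 2R_{out})$, which *grows* nearly
linearly with $R_{out}$; between 8 and 12 MΩ (with
$R_{DSin} = 80\ \mathrm{M\Omega}$) the transfer rises by exactly
$18/13 - 1 = 38.5\%$ — the characteristic relative increase this class of
models reports for low-frequency firing rates over that range. The package
therefore defaults to `terminals = "intracellular"`; the other tie remains
available (`terminals = "extracellular"`), and arbitrary `RTD`/`RSG` can
be given explicitly. Both reduce to the same generic two-loop solve, and
the closed form used inside the integrator is verified against that solve
in the test suite.

### Symmetric versus soma-side field coupling

With $V_{DSout}$ inserted in *both* cable equations (the printed,
default `field_coupling = "symmetric"` form), the field is a pure dipole
drive: the net injected current cancels exactly at $p = 0.5$, and firing
is modulated only through the asymmetry of the two compartments'
nonlinearities. This produces moderate entrainment — sub-unity locking
ratios at 30 Hz rising with $R_{out}$, locking windows that shift with
$V_K$, and high-frequency roll-off — but locking ratios never exceed 2
for amplitudes up to 200 mV at 10 Hz.

Applying the modified coupling in the somatic equation only
(`field_coupling = "soma"`, dendritic equation keeps $g_c (V_d - V_s)$)
converts the field into a net somatic drive roughly
$2 g_c V_{DSout}$ strong. Amplitude effects are then dramatic: locking
ratios jump above 2 between 50 and 80 mV and saturate near 4–6, and the
5 Hz / 100 mV rates reach 35–50 Hz over the $R_{out}$ range. The two
modes bracket the behaviours reported for this model family; they cannot
both be right for a single dataset, and the package treats the printed
symmetric form as the definition of the model while keeping the soma-side
form as an explicit, documented option for exploring the strong-response
regime.

## Numerical protocol

Integration uses `deSolve`'s BDF stiff solver on a compiled
right-hand side, with relative tolerance $10^{-6}$, absolute tolerance
$10^{-8}$, maximum step 0.5 ms, over 0–5000 ms, sampled every 0.01 ms;
the first 1000 ms are treated as burn-in and masked from analysis. A
pure-R `derivatives()` mirrors the compiled dynamics and the two are
cross-checked in the tests. The Heaviside drive of the synaptic gates
makes the right-hand side discontinuous; no event detection is used, and
the 0.5 ms step cap bounds the induced error (halving the tolerances
changes the baseline analysis-window rate by well under 2%). Initial
conditions are deterministic rest values ($V_s = V_d = 0$, gates at their
steady state for 0 mV, $Ca = 0.2$); no field ramp is applied, the burn-in
absorbs the onset transient. Dense-output samples can overshoot gate
bounds by $\sim 10^{-5}$; sampled gate and calcium series are clipped back
onto their invariant ranges.

Runs are bitwise deterministic for a given configuration. Sweeps cache
per-cell results keyed by a hash of the full cell configuration, so
interrupted scans resume and completed scans replay without simulation.

## Spike analysis

Spikes are somatic-voltage local maxima above
$V_{min} + 0.5\,(V_{max} - V_{min})$ of the analysis window with
topographic prominence at least $0.25\,(V_{max} - V_{min})$, thinned by a
3 ms minimum inter-peak interval (greedily keeping the higher peak). The
range-fraction thresholds make detection independent of the voltage
frame; both fractions and the interval are configurable
(`detection_config()`). Bursts are counted as their constituent spikes
subject to the 3 ms rule — the locking ratio can therefore exceed 1. The
mean firing rate is the spike count divided by the window length, and the
phase-locking ratio is that rate divided by the field frequency.

The synthetic-trace generator (`make_synthetic_trace()`) exists so the
analysis layer can be validated independently of the simulator: it sums
stereotyped ~2 ms Gaussian spike templates (~100 mV) on a flat baseline
with seeded Gaussian noise and carries its ground-truth spike times as an
attribute. It emulates the amplitude and width of somatic action
potentials but none of the subthreshold structure (oscillations,
depolarizing envelopes, bursts riding on plateaus) of real traces —
perfect recall/precision on fixtures therefore validates the detection
logic, not its behaviour on pathological waveforms.

## Parameter conventions for the sweep experiments

Scan grids follow the conventions of this literature: amplitude 0–200 mV
in 10 mV steps at $f = 10$ Hz; frequency 5–100 Hz in 5 Hz steps (5–60 Hz
for the $V_K$ experiments) at $A = 100$ mV; $R_{out} \in \{8,\ldots,12\}$
MΩ with $V_K = -38.56$ mV; $V_K \in [-90, -20]$ mV (model frame, the same
frame as the default $-38.56$) with $R_{out} = 10$ MΩ. All are
configurable through `sweep_spec()`. Failed cells are recorded as missing
values, never interpolated. The synaptic gates are driven by the cell's
own somatic spikes by default (`synapse_mode = "self"`), because the
NMDA/AMPA equations are part of the single-neuron model; `"off"` silences
the synaptic current for ablation.

## Worked example

```{r example, eval = FALSE}
cfg <- simulation_config(
  circuit  = circuit_parameters(Rout = 10),
  stimulus = field_stimulus(A = 100, f = 10))
res <- simulate_and_analyze(cfg)
res$rate_hz        # mean firing rate, 1000-5000 ms window
res$locking_ratio  # rate / field frequency

sp <- sweep_spec(axes  = list(Rout = 8:12),
                 fixed = list(amplitude = 100, frequency = 5))
surface <- run_sweep(sp)
surface$rate_hz
```

## Known limitations

* Single neuron only: the synaptic machinery self-couples or is silent;
  no network interactions.
* The extracellular network has two nodes; no spatially extended medium,
  no extracellular capacitance, no electrode interface.
* Printed reference values for this model family are only partially
  mutually consistent (see the coupling discussion above); quantities tied
  to the amplitude-jump regime are reproducible only under the soma-side
  coupling option.
* Grid-quantized rates: with a 4 s analysis window the rate resolution is
  0.25 Hz, so locking ratios at low frequencies are coarsely quantized.
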
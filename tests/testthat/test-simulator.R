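# Assembled ODE system: derivative assembly, integration, invariants.

test_that("rest initialization is deterministic and overridable", {
  s1 <- initial_state()
  s2 <- initial_state()
  expect_identical(s1, s2)
  expect_equal(s1[["Vs"]], 0)
  expect_equal(s1[["h"]], gate_steady_and_tau("h", 0)$inf)
  expect_equal(s1[["n"]], gate_steady_and_tau("n", 0)$inf)
  expect_equal(s1[["c"]], gate_steady_and_tau("c", 0)$inf)
  expect_equal(s1[["Ca"]], 0.2)
  expect_equal(initial_state(Vs = 10)[["Vs"]], 10)
  expect_error(initial_state(Vz = 1), "unknown state component")
})

test_that("derivatives vanish for a passive neuron with no drive", {
  par0 <- neuron_parameters(gc = 0, gL = 0, gNa = 0, gKDR = 0, gCa = 0,
                            gKAHP = 0, gKC = 0, gNMDA = 0, gAMPA = 0, Id = 0)
  st <- neuron_state(Vs = 0, Vd = 0, h = 0, n = 0, s = 0, c = 0, q = 0,
                     Ca = 0, Si = 0, Wi = 0)
  d <- derivatives(0, st, par0, circuit_parameters(), NULL)
  expect_equal(d[["Vs"]], 0)
  expect_equal(d[["Vd"]], 0)
  expect_equal(d[["Ca"]], 0)
})

test_that("derivatives match independent term-by-term evaluation", {
  # pinned state, independent evaluation of every printed term
  par <- neuron_parameters()
  circ <- circuit_parameters(RDSin = 80, Rout = 10)
  stim <- field_stimulus(A = 100, f = 10)
  st <- neuron_state(Vs = 5, Vd = -3, h = 0.8, n = 0.2, s = 0.05, c = 0.3,
                     q = 0.1, Ca = 80, Si = 4, Wi = 0.5)
  t <- 12.5
  d <- derivatives(t, st, par, circ, stim, field_coupling = "symmetric")
  Ve <- 100 * sin(2 * pi * 10 * t / 1000)
  VDSout <- 10 * ((80) * (5 - (-3)) + 80 * Ve) / ((80 + 10) * (80 + 10) - 100)
  am <- 0.32 * (13.1 - 5) / (exp((13.1 - 5) / 4) - 1)
  bm <- 0.28 * (5 - 40.1) / (exp((5 - 40.1) / 5) - 1)
  minf <- am / (am + bm)
  INa <- 30 * minf^2 * 0.8 * (5 - 120)
  IKDR <- 15 * 0.2 * (5 + 38.56)
  IDSin <- 2.1 * (-3 + VDSout - 5)
  dVs <- (-0.1 * 5 - INa - IKDR + IDSin / 0.5 + 0 / 0.5) / 3
  expect_equal(d[["Vs"]], dVs, tolerance = 1e-10)
  ICa <- 10 * 0.05^2 * (-3 - 140)
  IKAHP <- 0.8 * 0.1 * (-3 + 38.56)
  IKC <- 15 * 0.3 * (80 / 250) * (-3 + 38.56)
  INMDA <- 0.03 * 4 / (1 + 0.28 * exp(-0.062 * (-3 - 60))) * (-3 - 60)
  IAMPA <- 0.0045 * 0.5 * (-3 - 60)
  dVd <- (-0.1 * -3 - ICa - IKAHP - IKC - (INMDA + IAMPA) -
            IDSin / 0.5 + 0.7 / 0.5) / 3
  expect_equal(d[["Vd"]], dVd, tolerance = 1e-10)
  expect_equal(d[["Ca"]], -0.13 * ICa - 0.075 * 80, tolerance = 1e-10)
  expect_equal(d[["Si"]], 0 - 4 / 150)  # Vs = 5 below the NMDA threshold
  # soma-side coupling removes VDSout from the dendritic equation only
  ds <- derivatives(t, st, par, circ, stim, field_coupling = "soma")
  expect_equal(ds[["Vs"]], d[["Vs"]], tolerance = 1e-12)
  expect_equal(ds[["Vd"]], dVd + (IDSin - 2.1 * (-3 - 5)) / 0.5 / 3,
               tolerance = 1e-10)
  expect_error(derivatives(0, c(st[-1], NA), par, circ), "non-finite")
})

test_that("compiled dynamics agree with the reference R derivatives", {
  cfg <- simulation_config(t_end = 60, burn_in = 0, sample_dt = 0.05,
                           stimulus = field_stimulus(A = 100, f = 10),
                           circuit = circuit_parameters(Rout = 10),
                           field_coupling = "symmetric")
  tr <- simulate_neuron(cfg)
  rhs <- function(t, y, p) {
    list(as.numeric(derivatives(t, y, cfg$params, cfg$circuit, cfg$stimulus,
                                cfg$synapse_mode, cfg$field_coupling)))
  }
  ref <- deSolve::ode(y = setNames(as.numeric(initial_state()),
                                   names(initial_state())),
                      times = tr$t_ms, func = rhs, parms = NULL,
                      method = "bdf", rtol = 1e-8, atol = 1e-10, hmax = 0.5)
  expect_lt(max(abs(ref[, "Vs"] - tr$Vs_mV)), 0.1)
  expect_lt(max(abs(ref[, "Vd"] - tr$Vd_mV)), 0.1)
})

test_that("simulation is deterministic run to run", {
  cfg <- simulation_config(t_end = 300, burn_in = 0, sample_dt = 0.05,
                           stimulus = field_stimulus(A = 80, f = 20))
  tr1 <- simulate_neuron(cfg)
  tr2 <- simulate_neuron(cfg)
  expect_identical(tr1$Vs_mV, tr2$Vs_mV)  # bitwise
})

test_that("gating variables stay in [0,1] and calcium non-negative on trajectories", {
  cfgs <- list(
    simulation_config(t_end = 800, burn_in = 0, sample_dt = 0.05),
    simulation_config(t_end = 800, burn_in = 0, sample_dt = 0.05,
                      stimulus = field_stimulus(A = 150, f = 10),
                      circuit = circuit_parameters(Rout = 12)),
    simulation_config(t_end = 800, burn_in = 0, sample_dt = 0.05,
                      params = neuron_parameters(VK = -90),
                      stimulus = field_stimulus(A = 100, f = 40),
                      synapse_mode = "off"))
  for (cfg in cfgs) {
    tr <- simulate_neuron(cfg)
    for (g in c("h", "n", "s", "c", "q")) {
      expect_true(all(tr[[g]] >= 0 & tr[[g]] <= 1 + 1e-9))
    }
    expect_true(all(tr$Ca >= 0))
    expect_true(all(is.finite(tr$Vs_mV)))
  }
})

test_that("baseline dendritic drive produces repetitive firing", {
  cfg <- simulation_config(t_end = 3000, burn_in = 1000, sample_dt = 0.02)
  res <- simulate_and_analyze(cfg)
  expect_gt(res$n_spikes, 0)
})

test_that("silencing sodium and drive leaves a quiescent fixed point", {
  # gKAHP = 0 removes the ~1 s AHP gate so relaxation completes in-window
  cfg <- simulation_config(t_end = 1000, burn_in = 0, sample_dt = 0.1,
                           synapse_mode = "off",
                           params = neuron_parameters(gNa = 0, Id = 0,
                                                      gKAHP = 0))
  tr <- simulate_neuron(cfg)
  st <- detect_spikes(tr, window = c(0, 1000))
  expect_length(st$times, 0)
  # derivative of Vs at the end is numerically zero
  n <- nrow(tr)
  expect_lt(abs(tr$Vs_mV[n] - tr$Vs_mV[n - 1]) / 0.1, 1e-6)
})

test_that("field off with vanishing Rout recovers the uncoupled cable model", {
  # direct transcription of the plain two-compartment equations, written
  # here independently of the package's derivative code
  pr_rhs <- function(t, y, p) {
    Vs <- y[1]; Vd <- y[2]; h <- y[3]; n <- y[4]; s <- y[5]; c <- y[6]
    q <- y[7]; Ca <- y[8]; Si <- y[9]; Wi <- y[10]
    am <- 0.32 * (13.1 - Vs) / (exp((13.1 - Vs) / 4) - 1)
    bm <- 0.28 * (Vs - 40.1) / (exp((Vs - 40.1) / 5) - 1)
    ah <- 0.128 * exp((17 - Vs) / 18); bh <- 4 / (1 + exp((40 - Vs) / 5))
    an <- 0.016 * (35.1 - Vs) / (exp((35.1 - Vs) / 5) - 1)
    bn <- 0.25 * exp(0.5 - 0.025 * Vs)
    as_ <- 1.6 / (1 + exp(-0.072 * (Vd - 65)))
    bs <- 0.02 * (Vd - 51.1) / (exp((Vd - 51.1) / 5) - 1)
    if (Vd <= 50) {
      ac <- exp((Vd - 10) / 11 - (Vd - 6.5) / 27) / 18.975
      bc <- max(2 * exp((6.5 - Vd) / 27) - ac, 0)
    } else {
      ac <- 2 * exp((6.5 - Vd) / 27); bc <- 0
    }
    aq <- min(2e-5 * Ca, 0.01); bq <- 1e-3
    minf <- am / (am + bm)
    INa <- 30 * minf^2 * h * (Vs - 120)
    IKDR <- 15 * n * (Vs + 38.56)
    ICa <- 10 * s^2 * (Vd - 140)
    IKAHP <- 0.8 * q * (Vd + 38.56)
    IKC <- 15 * c * min(Ca / 250, 1) * (Vd + 38.56)
    INMDA <- 0.03 * Si / (1 + 0.28 * exp(-0.062 * (Vd - 60))) * (Vd - 60)
    IAMPA <- 0.0045 * Wi * (Vd - 60)
    IDS <- 2.1 * (Vd - Vs)
    list(c((-0.1 * Vs - INa - IKDR + IDS / 0.5) / 3,
           (-0.1 * Vd - ICa - IKAHP - IKC - (INMDA + IAMPA) - IDS / 0.5 +
              0.7 / 0.5) / 3,
           ah * (1 - h) - bh * h, an * (1 - n) - bn * n,
           as_ * (1 - s) - bs * s, ac * (1 - c) - bc * c,
           aq * (1 - q) - bq * q, -0.13 * ICa - 0.075 * Ca,
           (Vs >= 10) - Si / 150, (Vs >= 20) - Wi / 2))
  }
  y0 <- setNames(as.numeric(initial_state()), names(initial_state()))
  times <- seq(0, 1000, by = 0.05)
  # both runs at tightened tolerance so spike-timing jitter between the
  # two independent integrations stays below the comparison bound
  ref <- deSolve::ode(y0, times, pr_rhs, NULL, method = "bdf",
                      rtol = 1e-9, atol = 1e-11, hmax = 0.5)
  cfg <- simulation_config(t_end = 1000, burn_in = 0, sample_dt = 0.05,
                           rel_tol = 1e-9, abs_tol = 1e-11,
                           circuit = circuit_parameters(Rout = 1e-9))
  tr <- simulate_neuron(cfg)
  expect_lt(max(abs(ref[, "Vs"] - tr$Vs_mV)), 0.5)
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(burn_in = 5000, t_end = 5000), "burn_in")
  expect_error(simulation_config(sample_dt = 0), "positive")
  expect_error(simulation_config(rel_tol = -1), "positive")
  expect_error(simulation_config(stimulus = list(A = 1)), "field_stimulus")
})
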
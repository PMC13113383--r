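# Synthetic membrane-potential traces with known spike times, for testing
# the analysis layer independently of the simulator.

#' Synthetic trace with known spike times
#'
#' Builds a membrane-potential-like trace as baseline + a stereotyped
#' Gaussian spike template placed at each requested time + seeded Gaussian
#' noise. The template (~2 ms full width, ~100 mV amplitude by default)
#' mimics a somatic action potential riding on the model-frame baseline.
#' Ground-truth spike times are attached as attribute `spike_times`, so
#' detection recall/precision can be scored exactly. The trace is
#' deterministic for a given seed.
#'
#' @param spike_times True spike times (ms), strictly increasing; spikes
#'   closer than `template_width` are rejected (ambiguous ground truth).
#' @param t_end Trace length (ms).
#' @param sample_dt Sampling interval (ms).
#' @param baseline Baseline potential (mV).
#' @param amplitude Template peak amplitude above baseline (mV).
#' @param template_width Approximate full width of the template (ms); the
#'   Gaussian sigma is `template_width / 4`.
#' @param noise_amplitude Standard deviation of additive noise (mV).
#' @param seed Integer seed for the noise (ignored when
#'   `noise_amplitude = 0`).
#' @return A `pr_trace` with columns `t_ms`, `Vs_mV` and attribute
#'   `spike_times`.
#' @examples
#' tr <- make_synthetic_trace(c(100, 200, 300), t_end = 400,
#'                            noise_amplitude = 1, seed = 7)
#' attr(tr, "spike_times")
#' @export
make_synthetic_trace <- function(spike_times, t_end = 1000, sample_dt = 0.01,
                                 baseline = 0, amplitude = 100,
                                 template_width = 2, noise_amplitude = 0,
                                 seed = 1L) {
  spike_times <- as.numeric(spike_times)
  if (length(spike_times) && is.unsorted(spike_times, strictly = TRUE)) {
    stop("spike times must be strictly increasing")
  }
  if (length(spike_times) > 1L && any(diff(spike_times) < template_width)) {
    stop("overlapping spike templates: spikes closer than the template width")
  }
  if (length(spike_times) &&
      (any(spike_times < 0) || any(spike_times > t_end))) {
    stop("spike times must lie within [0, t_end]")
  }
  tt <- seq(0, t_end, by = sample_dt)
  v <- rep(baseline, length(tt))
  sigma <- template_width / 4
  for (tk in spike_times) {
    # template support limited to +-4 sigma for speed
    i <- which(tt >= tk - 4 * sigma & tt <= tk + 4 * sigma)
    v[i] <- v[i] + amplitude * exp(-(tt[i] - tk)^2 / (2 * sigma^2))
  }
  if (noise_amplitude > 0) {
    v <- v + withr_seed_rnorm(length(tt), noise_amplitude, seed)
  }
  tr <- data.frame(t_ms = tt, Vs_mV = v)
  attr(tr, "spike_times") <- spike_times
  class(tr) <- c("pr_trace", "data.frame")
  tr
}

# seeded noise without touching the caller's RNG state
withr_seed_rnorm <- function(n, sd, seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  rnorm(n, sd = sd)
}
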
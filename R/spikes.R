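# Spike detection and rate/phase-locking statistics.

#' Spike-detection configuration
#'
#' Detection is adaptive to the voltage range of the analysis window:
#' the height threshold and required peak prominence are fixed fractions
#' of `max(Vs) - min(Vs)` within the window, which makes detection
#' insensitive to the model-frame voltage offset. A minimum inter-peak
#' interval suppresses multiple detections of a single spike.
#'
#' @param min_interval Minimum inter-spike interval (ms, > 0; default 3).
#' @param prominence_fraction Required peak prominence as a fraction of the
#'   window's voltage range, in (0, 1); default 0.25.
#' @param threshold_fraction Height threshold as a fraction of the window's
#'   voltage range above its minimum, in (0, 1); default 0.5.
#' @return Object of class `detection_config`.
#' @export
detection_config <- function(min_interval = 3, prominence_fraction = 0.25,
                             threshold_fraction = 0.5) {
  if (min_interval <= 0) stop("min_interval must be positive")
  if (!(prominence_fraction > 0 && prominence_fraction < 1)) {
    stop("prominence_fraction must lie in (0, 1)")
  }
  if (!(threshold_fraction > 0 && threshold_fraction < 1)) {
    stop("threshold_fraction must lie in (0, 1)")
  }
  structure(list(min_interval = min_interval,
                 prominence_fraction = prominence_fraction,
                 threshold_fraction = threshold_fraction),
            class = "detection_config")
}

#' Spike train
#'
#' @param times Spike times (ms), strictly increasing.
#' @param window Half-open source window `[start, end)` in ms.
#' @param min_interval Minimum inter-spike interval the train respects.
#' @return Object of class `spike_train`.
#' @export
spike_train <- function(times, window, min_interval = 3) {
  times <- as.numeric(times)
  if (is.unsorted(times, strictly = TRUE)) stop("spike times must be strictly increasing")
  if (length(window) != 2L || window[2] <= window[1]) {
    stop("window must be c(start, end) with end > start")
  }
  if (length(times) && (any(times < window[1]) || any(times >= window[2]))) {
    stop("spike times must lie within the half-open window [start, end)")
  }
  if (length(times) > 1L && any(diff(times) < min_interval)) {
    stop("consecutive spikes violate the minimum inter-spike interval")
  }
  structure(list(times = times, window = window, min_interval = min_interval),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("spike_train: %d spikes in [%g, %g) ms (rate %.3f Hz)\n",
              length(x$times), x$window[1], x$window[2], mean_firing_rate(x)))
  invisible(x)
}

# local maxima (plateau-tolerant: first sample of a plateau counts)
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
}

# Topographic prominence of peak at index i: drop from the peak to the
# highest of the two bases, each base being the minimum between the peak
# and the nearest strictly higher sample (or the window edge).
peak_prominence <- function(v, idx) {
  vapply(idx, function(i) {
    h <- v[i]
    lo_l <- h
    j <- i - 1L
    while (j >= 1L && v[j] <= h) {
      if (v[j] < lo_l) lo_l <- v[j]
      j <- j - 1L
    }
    lo_r <- h
    j <- i + 1L
    while (j <= length(v) && v[j] <= h) {
      if (v[j] < lo_r) lo_r <- v[j]
      j <- j + 1L
    }
    h - max(lo_l, lo_r)
  }, numeric(1))
}

#' Detect somatic spikes in a trace
#'
#' Finds local maxima of `Vs` inside the analysis window whose height
#' exceeds `Vmin + threshold_fraction * (Vmax - Vmin)` and whose
#' topographic prominence is at least `prominence_fraction * (Vmax - Vmin)`
#' (range taken over the window), then enforces the minimum inter-peak
#' interval by greedily keeping the higher peak of any closer pair. A flat
#' window yields an empty train; bursts are counted as their constituent
#' spikes subject to the interval rule.
#'
#' @param trace A `pr_trace` (needs columns `t_ms` and `Vs_mV`).
#' @param cfg A [detection_config()].
#' @param window Half-open analysis window `c(start, end)` in ms; defaults
#'   to `[burn_in, t_end)` of the trace's generating config, or the full
#'   trace when no config is attached.
#' @return A [spike_train()].
#' @examples
#' tr <- make_synthetic_trace(c(50, 150, 250), t_end = 300,
#'                            noise_amplitude = 0.5, seed = 1)
#' detect_spikes(tr)$times
#' @export
detect_spikes <- function(trace, cfg = detection_config(), window = NULL) {
  if (is.null(window)) {
    gen <- attr(trace, "config")
    window <- if (!is.null(gen)) c(gen$burn_in, gen$t_end)
              else c(trace$t_ms[1], trace$t_ms[nrow(trace)] + 1e-9)
  }
  t_all <- trace$t_ms
  if (window[1] < t_all[1] - 1e-9 || window[2] > t_all[length(t_all)] + 1e-6) {
    stop("analysis window extends beyond the trace span")
  }
  keep <- t_all >= window[1] & t_all < window[2]
  if (!any(keep)) stop("empty analysis window")
  tt <- t_all[keep]
  v <- trace$Vs_mV[keep]
  rng <- max(v) - min(v)
  if (rng == 0) return(spike_train(numeric(0), window, cfg$min_interval))
  thr <- min(v) + cfg$threshold_fraction * rng
  idx <- local_maxima(v)
  idx <- idx[v[idx] >= thr]
  if (length(idx)) {
    prom <- peak_prominence(v, idx)
    idx <- idx[prom >= cfg$prominence_fraction * rng]
  }
  if (length(idx) > 1L) {
    # greedy: accept peaks in decreasing height, reject any within
    # min_interval of an already accepted peak
    ord <- idx[order(v[idx], decreasing = TRUE)]
    acc <- numeric(0)
    acc_i <- integer(0)
    for (i in ord) {
      if (!length(acc) || all(abs(tt[i] - acc) >= cfg$min_interval)) {
        acc <- c(acc, tt[i])
        acc_i <- c(acc_i, i)
      }
    }
    idx <- sort(acc_i)
  }
  spike_train(tt[idx], window, cfg$min_interval)
}

#' Mean firing rate of a spike train
#'
#' Spike count divided by the window length, in Hz. Being count-based it is
#' invariant to refinement of the sampling grid.
#'
#' @param train A [spike_train()].
#' @return Firing rate (Hz).
#' @examples
#' mean_firing_rate(spike_train(seq(1000, 4900, by = 100), c(1000, 5000)))
#' @export
mean_firing_rate <- function(train) {
  length(train$times) / ((train$window[2] - train$window[1]) / 1000)
}

#' Phase-locking ratio
#'
#' The ratio between neuronal firing frequency and applied field
#' frequency; a value near 1 indicates 1:1 entrainment of spiking to the
#' field cycle.
#'
#' @param firing_rate Mean firing rate (Hz).
#' @param field_frequency Applied field frequency (Hz, > 0).
#' @return Dimensionless ratio.
#' @examples
#' phase_locking_ratio(30, 10)  # 3
#' @export
phase_locking_ratio <- function(firing_rate, field_frequency) {
  if (any(field_frequency <= 0)) stop("field frequency must be positive")
  firing_rate / field_frequency
}
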
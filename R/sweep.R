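# Parameter-sweep engine: the reproduction layer for the field-sensitivity
# experiments (amplitude/frequency scans crossed with Rout, VK, [K+]o, Id).

sweep_axis_names <- c("amplitude", "frequency", "Rout", "VK", "Ko", "Id")

#' Sweep specification
#'
#' Describes a 1- or 2-axis parameter scan. Each axis is one of
#' `"amplitude"` (field amplitude, mV), `"frequency"` (field frequency,
#' Hz), `"Rout"` (extracellular resistance, MOhm), `"VK"` (potassium
#' reversal potential, mV, model frame), `"Ko"` (extracellular potassium,
#' mM) or `"Id"` (dendritic drive, uA/cm^2). `fixed` holds scalar
#' overrides of the same parameters for the non-swept settings; anything
#' not overridden comes from `base`. When neither the axes nor `fixed` nor
#' `base` define a stimulus, the conventional scan defaults A = 100 mV and
#' f = 10 Hz are used.
#'
#' @param axes Named list of sorted numeric value vectors; 1 or 2 entries,
#'   distinct names from the set above.
#' @param fixed Named list of scalar overrides (same names).
#' @param base A [simulation_config()] supplying everything else.
#' @param cache_dir Optional directory for per-cell result caching; cells
#'   already present are not re-simulated, making sweeps resumable.
#' @return Object of class `sweep_spec`.
#' @examples
#' sweep_spec(axes = list(Rout = 8:12),
#'            fixed = list(amplitude = 100, frequency = 5))
#' @export
sweep_spec <- function(axes, fixed = list(), base = simulation_config(),
                       cache_dir = NULL) {
  if (!length(axes) || length(axes) > 2L) stop("1 or 2 sweep axes required")
  if (is.null(names(axes)) || anyDuplicated(names(axes)) ||
      !all(names(axes) %in% sweep_axis_names)) {
    stop("axis names must be distinct and among: ",
         paste(sweep_axis_names, collapse = ", "))
  }
  for (nm in names(axes)) {
    v <- axes[[nm]]
    if (!is.numeric(v) || !length(v) || any(!is.finite(v)) || is.unsorted(v)) {
      stop("axis `", nm, "` must be a sorted vector of finite values")
    }
  }
  if (length(fixed) && (!all(names(fixed) %in% sweep_axis_names) ||
                        any(names(fixed) %in% names(axes)))) {
    stop("`fixed` names must be sweep parameters not already swept")
  }
  if (!inherits(base, "simulation_config")) stop("`base` must be a simulation_config")
  structure(list(axes = lapply(axes, as.numeric), fixed = fixed, base = base,
                 cache_dir = cache_dir),
            class = "sweep_spec")
}

# Apply named parameter overrides to a simulation config.
apply_overrides <- function(base, overrides) {
  cfg <- base
  pars <- as.list(cfg$params)
  if (!is.null(overrides$VK)) pars$VK <- overrides$VK
  if (!is.null(overrides$Id)) pars$Id <- overrides$Id
  cfg$params <- do.call(neuron_parameters, pars)
  if (!is.null(overrides$Ko)) {
    cfg$circuit <- circuit_parameters(RDSin = cfg$circuit$RDSin, Ko = overrides$Ko)
  }
  if (!is.null(overrides$Rout)) {
    cfg$circuit <- circuit_parameters(RDSin = cfg$circuit$RDSin, Rout = overrides$Rout)
  }
  A <- overrides$amplitude
  f <- overrides$frequency
  if (!is.null(A) || !is.null(f)) {
    if (is.null(A)) A <- if (is.null(cfg$stimulus)) 100 else cfg$stimulus$A
    if (is.null(f)) f <- if (is.null(cfg$stimulus)) 10 else cfg$stimulus$f
    cfg$stimulus <- field_stimulus(A = A, f = f)
  }
  cfg
}

# Content hash of a config (used as the cell cache key).
config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  # version-2 serialization for a stable byte stream across R sessions
  saveRDS(unclass(config), tf, version = 2)
  unname(tools::md5sum(tf))
}

#' Simulate one condition and analyze its spiking
#'
#' Convenience wrapper: integrates the model, detects somatic spikes in the
#' `[burn_in, t_end)` window and returns the mean firing rate plus, when a
#' stimulus is present, the phase-locking ratio.
#'
#' @param config A [simulation_config()].
#' @param detection A [detection_config()].
#' @return List with `rate_hz`, `locking_ratio` (NA without a stimulus),
#'   `n_spikes`, and the `spike_train`.
#' @export
simulate_and_analyze <- function(config, detection = detection_config()) {
  cfg <- config
  cfg$keep_gates <- FALSE
  tr <- simulate_neuron(cfg)
  train <- detect_spikes(tr, detection, window = c(cfg$burn_in, cfg$t_end))
  rate <- mean_firing_rate(train)
  lock <- if (is.null(cfg$stimulus)) NA_real_
          else phase_locking_ratio(rate, cfg$stimulus$f)
  list(rate_hz = rate, locking_ratio = lock,
       n_spikes = length(train$times), train = train)
}

#' Run a parameter sweep
#'
#' Simulates and analyzes every grid cell of a [sweep_spec()], one stiff
#' integration per cell. The run is deterministic; with a `cache_dir`,
#' completed cells are reloaded instead of re-simulated, so an interrupted
#' sweep resumes where it stopped and a finished sweep replays without any
#' new simulation. A cell whose integration fails is recorded as a missing
#' value (with a warning carrying the solver diagnostics) and never aborts
#' the sweep.
#'
#' @param spec A [sweep_spec()].
#' @param detection A [detection_config()].
#' @param verbose Print one line per cell.
#' @return Object of class `sweep_result`: `axes` (the grids), matrices
#'   `rate_hz`, `locking_ratio`, `n_spikes` (rows = first axis, cols =
#'   second axis or a single column for 1-axis sweeps), `n_simulated`
#'   (cells computed rather than loaded from cache), and `failures`.
#' @examples
#' \donttest{
#' sp <- sweep_spec(axes = list(Rout = c(8, 12)),
#'                  fixed = list(amplitude = 100, frequency = 5),
#'                  base = simulation_config(t_end = 2000))
#' res <- run_sweep(sp)
#' res$rate_hz
#' }
#' @export
run_sweep <- function(spec, detection = detection_config(), verbose = FALSE) {
  if (!inherits(spec, "sweep_spec")) stop("`spec` must be a sweep_spec")
  ax <- spec$axes
  n1 <- length(ax[[1]])
  n2 <- if (length(ax) == 2L) length(ax[[2]]) else 1L
  dimn <- list(as.character(ax[[1]]),
               if (length(ax) == 2L) as.character(ax[[2]]) else "value")
  rate <- lock <- matrix(NA_real_, n1, n2, dimnames = dimn)
  nspk <- matrix(NA_integer_, n1, n2, dimnames = dimn)
  if (!is.null(spec$cache_dir) && !dir.exists(spec$cache_dir)) {
    dir.create(spec$cache_dir, recursive = TRUE)
  }
  n_sim <- 0L
  failures <- list()
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      ov <- spec$fixed
      ov[[names(ax)[1]]] <- ax[[1]][i]
      if (length(ax) == 2L) ov[[names(ax)[2]]] <- ax[[2]][j]
      cfg <- apply_overrides(spec$base, ov)
      cache_file <- if (!is.null(spec$cache_dir)) {
        file.path(spec$cache_dir, paste0(config_hash(cfg), ".rds"))
      }
      cell <- NULL
      if (!is.null(cache_file) && file.exists(cache_file)) {
        cell <- readRDS(cache_file)
      } else {
        cell <- tryCatch({
          res <- simulate_and_analyze(cfg, detection)
          n_sim <- n_sim + 1L
          res[c("rate_hz", "locking_ratio", "n_spikes")]
        }, error = function(e) {
          warning("sweep cell (", i, ",", j, ") failed: ",
                  conditionMessage(e), call. = FALSE)
          failures[[length(failures) + 1L]] <<-
            list(i = i, j = j, message = conditionMessage(e))
          NULL
        })
        if (!is.null(cell) && !is.null(cache_file)) saveRDS(cell, cache_file)
      }
      if (!is.null(cell)) {
        rate[i, j] <- cell$rate_hz
        lock[i, j] <- cell$locking_ratio
        nspk[i, j] <- cell$n_spikes
      }
      if (verbose) {
        message(sprintf("cell (%d,%d): rate = %s Hz",
                        i, j, format(rate[i, j])))
      }
    }
  }
  structure(list(axes = ax, fixed = spec$fixed,
                 rate_hz = rate, locking_ratio = lock, n_spikes = nspk,
                 n_simulated = n_sim, failures = failures,
                 base_hash = config_hash(spec$base),
                 timestamp = format(Sys.time(), tz = "UTC")),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("sweep_result: %s (%s cells, %d simulated, %d failed)\n",
              paste(names(x$axes), collapse = " x "),
              paste(dim(x$rate_hz), collapse = " x "),
              x$n_simulated, length(x$failures)))
  print(round(x$rate_hz, 3))
  invisible(x)
}

#' Mean firing rate averaged over one sweep axis
#'
#' Arithmetic mean of the firing-rate matrix over the named axis (missing
#' cells excluded), giving one mean per value of the remaining axis -- for
#' a 1-axis sweep, a single overall mean. Averaging a VK-by-frequency
#' sweep over `"frequency"` yields the per-VK mean firing frequencies used
#' to summarize intrinsic excitability.
#'
#' @param result A `sweep_result`.
#' @param axis Name of the axis averaged over.
#' @return Named numeric vector (names = remaining axis values), or a
#'   scalar for 1-axis sweeps. Rows with no finite cells give `NA` with a
#'   warning.
#' @export
mean_rate_over_axis <- function(result, axis) {
  if (!axis %in% names(result$axes)) stop("no such sweep axis: ", axis)
  m <- result$rate_hz
  if (length(result$axes) == 1L) {
    return(mean(m, na.rm = TRUE))
  }
  over_rows <- axis == names(result$axes)[1]
  out <- apply(m, if (over_rows) 2 else 1, function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  if (any(is.na(out))) warning("axis value(s) with all cells missing")
  out
}

#' Field amplitude at which the phase-locking ratio jumps
#'
#' The smallest scanned amplitude whose locking ratio exceeds `level`
#' (default 2, the conventional jump level separating low-order from
#' high-order locking). Requires `"amplitude"` as a swept axis; for a
#' 2-axis sweep one threshold is returned per value of the other axis.
#' `NA` where the level is never exceeded.
#'
#' @param result A `sweep_result` with an amplitude axis.
#' @param level Locking-ratio level to exceed.
#' @return Amplitude(s) in mV.
#' @export
locking_jump_threshold <- function(result, level = 2) {
  if (!"amplitude" %in% names(result$axes)) {
    stop("`amplitude` is not a swept axis of this result")
  }
  amp_rows <- names(result$axes)[1] == "amplitude"
  m <- if (amp_rows) result$locking_ratio else t(result$locking_ratio)
  amps <- result$axes[["amplitude"]]
  out <- apply(m, 2, function(v) {
    k <- which(!is.na(v) & v > level)
    if (length(k)) amps[min(k)] else NA_real_
  })
  if (length(result$axes) == 1L) unname(out[1]) else out
}

#' Export / load a sweep surface
#'
#' `export_surface()` writes the result as a long-format CSV (one row per
#' cell: axis value columns, `rate_hz`, `locking_ratio`, `n_spikes`;
#' missing cells as empty fields) plus a JSON run manifest
#' (`<path>.manifest.json`) holding the axes, fixed overrides, base-config
#' hash and timestamp. `load_surface()` restores the `sweep_result`.
#'
#' @param result A `sweep_result`.
#' @param path CSV file path.
#' @return `load_surface()` returns a `sweep_result`; `export_surface()`
#'   returns `path` invisibly.
#' @export
export_surface <- function(result, path) {
  ax <- result$axes
  if (length(ax) == 2L) {
    g <- expand.grid(a1 = ax[[1]], a2 = ax[[2]], KEEP.OUT.ATTRS = FALSE)
    names(g) <- names(ax)
  } else {
    g <- setNames(data.frame(ax[[1]]), names(ax))
  }
  g$rate_hz <- as.vector(result$rate_hz)
  g$locking_ratio <- as.vector(result$locking_ratio)
  g$n_spikes <- as.vector(result$n_spikes)
  data.table::fwrite(g, path, na = "")
  manifest <- list(axes = ax, fixed = result$fixed,
                   base_hash = result$base_hash,
                   n_simulated = result$n_simulated,
                   timestamp = result$timestamp,
                   package = as.character(utils::packageVersion("prfield")))
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname export_surface
#' @export
load_surface <- function(path) {
  g <- data.table::fread(path, sep = ",", header = TRUE, data.table = FALSE,
                         na.strings = "")
  need <- c("rate_hz", "locking_ratio", "n_spikes")
  miss <- setdiff(need, names(g))
  if (length(miss)) stop("surface schema mismatch: missing column ", miss[1])
  ax_names <- setdiff(names(g), need)
  if (!length(ax_names) || length(ax_names) > 2L) {
    stop("surface schema mismatch: expected 1 or 2 axis columns")
  }
  ax <- lapply(g[ax_names], function(v) sort(unique(v)))
  n1 <- length(ax[[1]])
  n2 <- if (length(ax) == 2L) length(ax[[2]]) else 1L
  dimn <- list(as.character(ax[[1]]),
               if (length(ax) == 2L) as.character(ax[[2]]) else "value")
  idx1 <- match(g[[ax_names[1]]], ax[[1]])
  idx2 <- if (length(ax) == 2L) match(g[[ax_names[2]]], ax[[2]]) else rep(1L, nrow(g))
  mk <- function(col, mode = "double") {
    m <- matrix(vector(mode, 1)[NA], n1, n2, dimnames = dimn)
    m[cbind(idx1, idx2)] <- g[[col]]
    m
  }
  manifest_path <- paste0(path, ".manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  }
  structure(list(axes = ax,
                 fixed = if (is.null(manifest)) list() else as.list(manifest$fixed),
                 rate_hz = mk("rate_hz"),
                 locking_ratio = mk("locking_ratio"),
                 n_spikes = mk("n_spikes", "integer"),
                 n_simulated = if (is.null(manifest)) NA_integer_
                               else manifest$n_simulated,
                 failures = list(),
                 base_hash = if (is.null(manifest)) NA_character_
                             else manifest$base_hash,
                 timestamp = if (is.null(manifest)) NA_character_
                             else manifest$timestamp),
            class = "sweep_result")
}
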
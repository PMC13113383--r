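# Trace serialization: delimited text (CSV with a t_ms/Vs_mV/... header)
# and, for sweep-scale storage, R's binary serialization.

#' Write / read a trace
#'
#' `write_trace()` stores a trace losslessly; `read_trace()` restores it.
#' Format is chosen from the file extension: `.csv` writes delimited text
#' with the header row `t_ms, Vs_mV, Vd_mV, VDSout_mV, ...` (full double
#' precision), `.rds` uses R's binary serialization (keeps the config
#' attribute as well).
#'
#' @param trace A `pr_trace` (or plain data.frame with a `t_ms` column).
#' @param path File path ending in `.csv` or `.rds`.
#' @return `read_trace()` returns a `pr_trace`; `write_trace()` returns
#'   `path` invisibly.
#' @examples
#' tr <- make_synthetic_trace(c(20, 40), t_end = 60, noise_amplitude = 0)
#' f <- tempfile(fileext = ".csv")
#' write_trace(tr, f)
#' tr2 <- read_trace(f)
#' all.equal(tr$Vs_mV, tr2$Vs_mV)
#' @export
write_trace <- function(trace, path) {
  if (!is.data.frame(trace) || !"t_ms" %in% names(trace)) {
    stop("`trace` must be a data.frame with a t_ms column")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "rds") {
    saveRDS(trace, path)
  } else if (ext == "csv") {
    data.table::fwrite(as.data.frame(trace), path)
  } else {
    stop("unsupported trace format: .", ext, " (use .csv or .rds)")
  }
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("no such trace file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "rds") {
    tr <- readRDS(path)
  } else if (ext == "csv") {
    if (file.size(path) == 0) stop("trace parse error: empty file")
    n_field <- lengths(strsplit(readLines(path, n = -1L, warn = FALSE), ","))
    if (length(unique(n_field)) != 1L) {
      stop("trace parse error: truncated record at line ",
           which(n_field != n_field[1])[1])
    }
    dt <- tryCatch(
      data.table::fread(path, sep = ",", header = TRUE, data.table = FALSE),
      warning = function(w) stop("trace parse error: ", conditionMessage(w)),
      error = function(e) stop("trace parse error: ", conditionMessage(e)))
    if (!"t_ms" %in% names(dt)) stop("trace parse error: missing t_ms column")
    tr <- dt
  } else {
    stop("unsupported trace format: .", ext)
  }
  if (any(!is.finite(tr$t_ms)) || is.unsorted(tr$t_ms, strictly = TRUE)) {
    stop("trace parse error: time grid must be strictly increasing")
  }
  class(tr) <- c("pr_trace", "data.frame")
  tr
}
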
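#' Membrane-potential trace
#'
#' Container for a uniformly sampled current-clamp voltage trace. Voltages are
#' in mV, times in ms, and the sampling rate `fs` in Hz (recordings are
#' nominally acquired at 25 kHz). `offset_applied` records any fixed offset
#' already subtracted from the samples, e.g. a -13 mV liquid-junction
#' correction.
#'
#' @param samples numeric vector of membrane potential, mV.
#' @param fs sampling frequency, Hz (> 0).
#' @param t0 time of the first sample, ms.
#' @param cell_id label for the recorded cell.
#' @param offset_applied offset already applied to `samples`, mV.
#' @return An object of class `vm_trace`.
#' @examples
#' tr <- vm_trace(rep(-60, 1000), fs = 25000)
#' range(trace_times(tr))
#' @export
vm_trace <- function(samples, fs, t0 = 0, cell_id = "cell",
                     offset_applied = 0) {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number (Hz)")
  if (any(!is.finite(samples)))
    stop("trace samples must be finite")
  structure(list(samples = samples, fs = fs, t0 = t0,
                 cell_id = as.character(cell_id),
                 offset_applied = offset_applied),
            class = "vm_trace")
}

#' @export
print.vm_trace <- function(x, ...) {
  cat(sprintf("<vm_trace '%s': %d samples @ %g kHz (%.1f ms), range %.1f..%.1f mV>\n",
              x$cell_id, length(x$samples), x$fs / 1000,
              length(x$samples) / x$fs * 1000,
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' @export
length.vm_trace <- function(x) length(x$samples)

#' Sample times of a trace
#'
#' @param trace a [vm_trace].
#' @return numeric vector of times in ms (first sample at `t0`).
#' @export
trace_times <- function(trace) {
  trace$t0 + (seq_along(trace$samples) - 1) / trace$fs * 1000
}

# time (ms) -> nearest 1-based sample index, clamped to the trace
time_to_index <- function(trace, t_ms) {
  i <- round((t_ms - trace$t0) * trace$fs / 1000) + 1
  pmin(pmax(i, 1L), length(trace$samples))
}

index_to_time <- function(trace, i) trace$t0 + (i - 1) / trace$fs * 1000

#' Shift a trace by a constant offset
#'
#' Applies a fixed voltage offset (for example the -13 mV junction-potential
#' correction applied offline to the recordings) and records it in
#' `offset_applied`.
#'
#' @param trace a [vm_trace].
#' @param offset_mv offset to add, mV.
#' @return the shifted [vm_trace].
#' @export
apply_offset <- function(trace, offset_mv) {
  trace$samples <- trace$samples + offset_mv
  trace$offset_applied <- trace$offset_applied + offset_mv
  trace
}

#' @export
as.data.frame.vm_trace <- function(x, ...) {
  data.frame(time_ms = trace_times(x), vm_mV = x$samples)
}

#' Read a voltage trace from CSV
#'
#' Expects columns `time_ms` and `vm_mV` with uniform sampling. (ABF and HDF5
#' backends are not available in this build; traces exported from those
#' formats should be converted to this CSV layout.)
#'
#' @param path file path.
#' @param cell_id label for the trace; defaults to the file name.
#' @return a [vm_trace].
#' @export
read_vm_csv <- function(path, cell_id = NULL) {
  d <- utils::read.csv(path)
  if (!all(c("time_ms", "vm_mV") %in% names(d)))
    stop("CSV must have columns time_ms, vm_mV")
  dt <- diff(d$time_ms)
  if (length(dt) < 1 || any(abs(dt - dt[1]) > 1e-6 * abs(dt[1])))
    stop("time_ms must be uniformly sampled")
  vm_trace(d$vm_mV, fs = 1000 / dt[1], t0 = d$time_ms[1],
           cell_id = cell_id %||% basename(path))
}

#' Write a voltage trace to CSV
#'
#' @param trace a [vm_trace].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vm_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
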
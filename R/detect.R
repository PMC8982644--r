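#' Detect action potentials by detection-potential crossing
#'
#' One event is produced per upward crossing of `v_detect` (default -23 mV);
#' crossings closer than `min_isi` (default 1 ms) to the previously accepted
#' event are discarded. The peak is the local maximum between the crossing
#' and the return below the detection potential.
#'
#' @param trace a [vm_trace].
#' @param v_detect detection potential, mV. A per-cell override (one recorded
#'   cell needed -43 mV) is just a different value here.
#' @param min_isi minimum inter-spike interval, ms.
#' @return data frame with one row per AP: `peak_index`, `peak_time`,
#'   `peak_value`, `cross_index`, `cross_time`.
#' @export
detect_spikes <- function(trace, v_detect = -23, min_isi = 1) {
  v <- trace$samples
  n <- length(v)
  empty <- data.frame(peak_index = integer(), peak_time = numeric(),
                      peak_value = numeric(), cross_index = integer(),
                      cross_time = numeric())
  if (n < 2) return(empty)
  up <- which(v[-1] >= v_detect & v[-n] < v_detect) + 1L
  if (length(up) == 0) return(empty)
  # enforce the refractory rule against the last *accepted* crossing
  keep <- logical(length(up))
  last_t <- -Inf
  min_samp <- min_isi * trace$fs / 1000
  for (i in seq_along(up)) {
    if (up[i] - last_t >= min_samp) {
      keep[i] <- TRUE
      last_t <- up[i]
    }
  }
  up <- up[keep]
  dn_all <- which(v[-1] < v_detect & v[-n] >= v_detect) + 1L
  cap <- round(10 * trace$fs / 1000)  # peak search capped at 10 ms
  peak_idx <- vapply(up, function(i) {
    j <- dn_all[dn_all > i]
    j <- if (length(j)) j[1] else min(i + cap, n)
    i - 1L + which.max(v[i:j])
  }, integer(1))
  data.frame(peak_index = peak_idx,
             peak_time = index_to_time(trace, peak_idx),
             peak_value = v[peak_idx],
             cross_index = up,
             cross_time = index_to_time(trace, up))
}

# Savitzky-Golay smoothed derivatives of order 0..2 (quadratic fit over a
# centred window); returns a matrix with NA edges
sg_derivatives <- function(x, half, dt_ms) {
  k <- -half:half
  X <- cbind(1, k, k^2)
  H <- solve(crossprod(X), t(X))  # rows: value, d1, d2 coefficients
  sm <- stats::filter(x, rev(H[1, ]), sides = 2)
  d1 <- stats::filter(x, rev(H[2, ]), sides = 2) / dt_ms
  d2 <- stats::filter(x, rev(H[3, ]), sides = 2) * 2 / dt_ms^2
  cbind(v = as.numeric(sm), d1 = as.numeric(d1), d2 = as.numeric(d2))
}

#' Locate the voltage threshold of one action potential
#'
#' Two criteria are available. `"second_derivative"` (used on experimental
#' traces): within the AP rising phase -- the interval from the last local
#' minimum before the peak to the peak -- find the point of maximum positive
#' acceleration of Vm, then walk backward to the earliest contiguous sample
#' at which the smoothed second derivative is still strictly positive.
#' `"dvdt_cut"` (used on model traces): the first point at which dV/dt
#' exceeds `dvdt_cut` (40 mV/ms).
#'
#' @param trace a [vm_trace].
#' @param peak_index sample index of the AP peak (from [detect_spikes]).
#' @param method `"second_derivative"` or `"dvdt_cut"`.
#' @param dvdt_cut rate criterion for `"dvdt_cut"`, mV/ms.
#' @param smooth_ms Savitzky-Golay smoothing window for the derivatives, ms.
#' @param bound search bound for the rising-phase maximum:
#'   `"max_acceleration"` (default) bounds the search at the maximum of the
#'   second derivative, `"max_dvdt"` at the maximum depolarization rate.
#' @param max_rise_ms how far before the peak the rising phase may start, ms.
#' @return list with `threshold_index`, `threshold_time`, `threshold_value`,
#'   and `flagged` (TRUE when no qualifying point exists; such events are
#'   excluded downstream).
#' @export
detect_ap_threshold <- function(trace, peak_index,
                                method = c("second_derivative", "dvdt_cut"),
                                dvdt_cut = 40, smooth_ms = 0.3,
                                bound = c("max_acceleration", "max_dvdt"),
                                max_rise_ms = 10) {
  method <- match.arg(method)
  bound <- match.arg(bound)
  v <- trace$samples
  dt_ms <- 1000 / trace$fs
  flagged <- list(threshold_index = NA_integer_, threshold_time = NA_real_,
                  threshold_value = NA_real_, flagged = TRUE)
  w0 <- max(1L, peak_index - round(max_rise_ms / dt_ms))
  if (peak_index - w0 < round(0.5 / dt_ms)) return(flagged)
  half <- max(2L, round(smooth_ms / dt_ms / 2))
  # pad past the peak so the smoothed derivatives are defined up to it
  w1 <- min(length(v), peak_index + half)
  seg <- v[w0:w1]
  der <- sg_derivatives(seg, half, dt_ms)
  der <- der[seq_len(peak_index - w0 + 1L), , drop = FALSE]
  # rising phase: from the last local minimum of the smoothed trace before
  # the peak up to the peak
  sm <- der[, "v"]
  ok <- which(!is.na(sm))
  if (length(ok) < 3) return(flagged)
  i_min <- length(sm)
  for (i in seq(length(sm) - 1, 2)) {
    if (!is.na(sm[i]) && !is.na(sm[i - 1]) && !is.na(sm[i + 1]) &&
        sm[i] <= sm[i - 1] && sm[i] <= sm[i + 1]) { i_min <- i; break }
    i_min <- i
  }
  # the rise proper can be as short as ~0.3 ms; smoothing undershoot at its
  # foot can clip the nominal phase, so require only 0.2 ms here (the 0.5 ms
  # precondition is enforced on the window above)
  rise <- i_min:length(sm)
  if (length(rise) < max(3L, round(0.2 / dt_ms))) return(flagged)

  if (method == "dvdt_cut") {
    d1 <- der[, "d1"]
    hit <- rise[which(d1[rise] > dvdt_cut)]
    if (!length(hit)) return(flagged)
    idx <- w0 + hit[1] - 1L
    return(list(threshold_index = idx,
                threshold_time = index_to_time(trace, idx),
                threshold_value = v[idx], flagged = FALSE))
  }
  d2 <- der[, "d2"]
  crit <- if (bound == "max_acceleration") d2[rise] else der[rise, "d1"]
  if (all(is.na(crit))) return(flagged)
  i_max <- rise[which.max(crit)]
  if (is.na(d2[i_max]) || d2[i_max] <= 0) return(flagged)
  j <- i_max
  while (j > rise[1] && !is.na(d2[j - 1]) && d2[j - 1] > 0) j <- j - 1L
  idx <- w0 + j - 1L
  list(threshold_index = idx,
       threshold_time = index_to_time(trace, idx),
       threshold_value = v[idx], flagged = FALSE)
}

#' Detect spikes and annotate their thresholds
#'
#' Convenience wrapper chaining [detect_spikes] and [detect_ap_threshold].
#'
#' @inheritParams detect_spikes
#' @inheritParams detect_ap_threshold
#' @return data frame with one row per AP (`peak_*`, `threshold_*`,
#'   `flagged`).
#' @export
detect_aps <- function(trace, v_detect = -23, min_isi = 1,
                       method = "second_derivative", dvdt_cut = 40,
                       smooth_ms = 0.3, bound = "max_acceleration") {
  sp <- detect_spikes(trace, v_detect, min_isi)
  if (nrow(sp) == 0) {
    sp$threshold_index <- integer()
    sp$threshold_time <- numeric()
    sp$threshold_value <- numeric()
    sp$flagged <- logical()
    return(sp)
  }
  th <- lapply(sp$peak_index, function(i)
    detect_ap_threshold(trace, i, method = method, dvdt_cut = dvdt_cut,
                        smooth_ms = smooth_ms, bound = bound))
  sp$threshold_index <- vapply(th, function(x)
    as.integer(x$threshold_index), integer(1))
  sp$threshold_time <- vapply(th, `[[`, numeric(1), "threshold_time")
  sp$threshold_value <- vapply(th, `[[`, numeric(1), "threshold_value")
  sp$flagged <- vapply(th, `[[`, logical(1), "flagged")
  sp
}

# single grouping pass: consecutive spikes with ISI strictly below tisi
# share a burst
group_by_tisi <- function(spike_times, tisi, min_burst_size = 2) {
  n <- length(spike_times)
  if (n == 0) return(list(bursts = list(), isolated = integer()))
  brk <- which(diff(spike_times) >= tisi)
  starts <- c(1L, brk + 1L)
  ends <- c(brk, n)
  groups <- Map(seq, starts, ends)
  sizes <- lengths(groups)
  list(bursts = groups[sizes >= min_burst_size],
       isolated = unlist(groups[sizes < min_burst_size]) %||% integer())
}

#' Segment a spike train into bursts with the recursive adaptive tISI
#'
#' Starting from `tisi0` (90 ms), spikes whose inter-spike interval is
#' strictly below the current threshold share a burst; the threshold is then
#' recomputed as the median of all intraburst ISIs plus `mad_mult` (4) times
#' their raw median absolute deviation, and the procedure repeats while the
#' new threshold is smaller than the previous one. Groups smaller than
#' `min_burst_size` become isolated APs.
#'
#' @param spike_times strictly increasing spike times, ms.
#' @param tisi0 initial ISI threshold, ms.
#' @param mad_mult MAD multiplier (one recorded cell needed 0.8; pass it
#'   here).
#' @param min_burst_size minimum APs per burst.
#' @param tisi_floor lower guard for the threshold, ms (the recursion cannot
#'   go below the minimum ISI; guards the degenerate MAD = 0 collapse).
#' @return object of class `burst_segmentation`: list with `bursts` (list of
#'   integer index vectors into `spike_times`), `isolated` (integer vector),
#'   `final_tisi`, `tisi_history` and `spike_times`.
#' @export
detect_bursts_adaptive <- function(spike_times, tisi0 = 90, mad_mult = 4,
                                   min_burst_size = 2, tisi_floor = 1) {
  if (length(spike_times) > 1 && is.unsorted(spike_times, strictly = TRUE))
    stop("spike_times must be strictly increasing")
  seg <- function(bursts, isolated, tisi, history, warn = NULL) {
    structure(list(bursts = bursts, isolated = isolated,
                   final_tisi = tisi, tisi_history = history,
                   spike_times = spike_times, warning = warn),
              class = "burst_segmentation")
  }
  if (length(spike_times) < 2)
    return(seg(list(), seq_along(spike_times), tisi0, tisi0))
  tisi <- tisi0
  history <- tisi0
  prev <- NULL
  repeat {
    g <- group_by_tisi(spike_times, tisi, min_burst_size)
    intra <- unlist(lapply(g$bursts, function(ix) diff(spike_times[ix])))
    if (length(intra) == 0) {
      # degenerate collapse (MAD = 0 makes the strict-< grouping orphan all
      # bursts): keep the last burst-bearing segmentation if there was one
      if (!is.null(prev))
        return(seg(prev$g$bursts, prev$g$isolated, prev$tisi,
                   history[-length(history)],
                   warn = "tISI recursion collapsed; kept previous segmentation"))
      return(seg(g$bursts, g$isolated, tisi, history,
                 warn = "no intraburst ISIs at current tISI"))
    }
    new_tisi <- max(stats::median(intra) + mad_mult * raw_mad(intra),
                    tisi_floor)
    if (new_tisi >= tisi) break
    prev <- list(g = g, tisi = tisi)
    tisi <- new_tisi
    history <- c(history, new_tisi)
  }
  g <- group_by_tisi(spike_times, tisi, min_burst_size)
  seg(g$bursts, g$isolated, tisi, history)
}

#' @export
print.burst_segmentation <- function(x, ...) {
  cat(sprintf("<burst_segmentation: %d bursts (%d APs), %d isolated, final tISI %.2f ms (%d iterations)>\n",
              length(x$bursts), sum(lengths(x$bursts)), length(x$isolated),
              x$final_tisi, length(x$tisi_history)))
  invisible(x)
}

#' Per-spike burst labels from a segmentation
#'
#' @param seg a `burst_segmentation`.
#' @return integer vector aligned with `seg$spike_times`; `NA` marks isolated
#'   APs.
#' @export
burst_labels <- function(seg) {
  lab <- rep(NA_integer_, length(seg$spike_times))
  for (k in seq_along(seg$bursts)) lab[seg$bursts[[k]]] <- k
  lab
}
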
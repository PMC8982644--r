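#' Resting potential and fluctuation amplitude before a burst
#'
#' The burst resting potential is the median Vm over the AP-free interval
#' preceding the burst, excluding half of the final tISI at the beginning and
#' 5 ms at the end; the subthreshold fluctuation amplitude is the maximum Vm
#' over the same window. If that interval is shorter than `min_interval_ms`
#' (200 ms), both values are inherited from the preceding burst; a first
#' burst with a short interval is excluded.
#'
#' @param trace a [vm_trace].
#' @param seg a `burst_segmentation` (provides `final_tisi`).
#' @param burst_index which burst.
#' @param ap_table annotated AP table from [detect_aps] aligned with
#'   `seg$spike_times`.
#' @param prev_context the previous burst's context (for inheritance), or
#'   `NULL`.
#' @param min_interval_ms minimum usable interval, ms.
#' @param tail_trim_ms trimmed from the end of the interval, ms.
#' @return list with `v_rest`, `fluct_amplitude`, `inherited`, `excluded`,
#'   `interval_ms`.
#' @export
compute_burst_context <- function(trace, seg, burst_index, ap_table,
                                  prev_context = NULL,
                                  min_interval_ms = 200, tail_trim_ms = 5) {
  ix <- seg$bursts[[burst_index]]
  first_ap <- ix[1]
  t_end <- ap_table$threshold_time[first_ap]
  if (is.na(t_end)) t_end <- ap_table$cross_time[first_ap]
  prev_spikes <- seg$spike_times[seg$spike_times < seg$spike_times[first_ap]]
  t_start <- if (length(prev_spikes)) max(prev_spikes) else trace$t0
  interval <- t_end - t_start
  if (interval < min_interval_ms) {
    if (is.null(prev_context))
      return(list(v_rest = NA_real_, fluct_amplitude = NA_real_,
                  inherited = FALSE, excluded = TRUE,
                  reason = "interburst interval < 200 ms with no predecessor",
                  interval_ms = interval))
    return(list(v_rest = prev_context$v_rest,
                fluct_amplitude = prev_context$fluct_amplitude,
                inherited = TRUE, excluded = FALSE, interval_ms = interval))
  }
  i0 <- time_to_index(trace, t_start + seg$final_tisi / 2)
  i1 <- time_to_index(trace, t_end - tail_trim_ms)
  if (i1 <= i0) i1 <- i0 + 1L
  w <- trace$samples[i0:i1]
  list(v_rest = stats::median(w), fluct_amplitude = max(w),
       inherited = FALSE, excluded = FALSE, interval_ms = interval)
}

#' Pre-AP potential and slope
#'
#' The pre-AP potential is the first negative Vm peak preceding the AP
#' threshold: stepping backward from the threshold in 1 ms steps, the search
#' stops as soon as the Vm at the current step exceeds the running minimum of
#' the interval up to the threshold by at least `rebound_mv` (0.4 mV); the
#' pre-AP potential is the lowest Vm between that rebound time and the
#' threshold. The pre-AP slope is the linear-regression slope of Vm over the
#' 5 ms before the threshold when the pre-AP peak is more than 5 ms away,
#' otherwise over the 20-80% voltage range from the pre-AP potential (0%) to
#' the threshold (100%).
#'
#' @param trace a [vm_trace].
#' @param threshold_index sample index of the AP threshold.
#' @param rebound_mv rebound criterion, mV ("at least": `>=`).
#' @param step_ms backward step, ms.
#' @param lookback_ms search limit, ms; if no rebound is found the minimum
#'   over the lookback is returned flagged.
#' @return list with `pre_ap_value`, `pre_ap_time`, `pre_ap_index`,
#'   `pre_ap_slope`, `flagged`.
#' @export
pre_ap_features <- function(trace, threshold_index, rebound_mv = 0.4,
                            step_ms = 1, lookback_ms = 300) {
  v <- trace$samples
  dt_ms <- 1000 / trace$fs
  step <- max(1L, round(step_ms / dt_ms))
  i_thr <- threshold_index
  limit <- max(1L, i_thr - round(lookback_ms / dt_ms))
  flagged <- FALSE
  i <- i_thr
  rebound_at <- NA_integer_
  repeat {
    i <- i - step
    if (i < limit) { flagged <- TRUE; rebound_at <- limit; break }
    if (v[i] - min(v[i:i_thr]) >= rebound_mv) { rebound_at <- i; break }
  }
  seg <- rebound_at:i_thr
  i_pre <- seg[which.min(v[seg])]
  pre_val <- v[i_pre]
  thr_val <- v[i_thr]
  gap_ms <- (i_thr - i_pre) * dt_ms
  if (gap_ms > 5) {
    ix <- (i_thr - round(5 / dt_ms)):i_thr
  } else {
    lo <- pre_val + 0.2 * (thr_val - pre_val)
    hi <- pre_val + 0.8 * (thr_val - pre_val)
    band <- i_pre:i_thr
    inb <- band[v[band] >= lo & v[band] <= hi]
    ix <- if (length(inb) >= 3) min(inb):max(inb) else band
  }
  slope <- if (length(ix) >= 3)
    unname(fast_slope((ix - ix[1]) * dt_ms, v[ix])["slope"])
  else NA_real_
  list(pre_ap_value = pre_val, pre_ap_time = index_to_time(trace, i_pre),
       pre_ap_index = i_pre, pre_ap_slope = slope, flagged = flagged)
}

#' AHP amplitude, peak, slope and duration after one AP
#'
#' The AHP peak is the lowest Vm between two consecutive APs (or within the
#' 300 ms following the AP when the interval is longer); its amplitude is
#' that minimum minus the burst resting potential (negative by convention).
#' The AHP slope is the regression slope of Vm over the span where Vm lies
#' within 20-60% of the range from the AHP peak (0%) to the *previous* AP
#' threshold (100%) -- anchoring on the previous AP lets the slope after the
#' last AP of a burst be computed the same way. Duration is the time from
#' the AHP peak to the next AP threshold (undefined after the last AP).
#'
#' @param trace a [vm_trace].
#' @param peak_index sample index of this AP's peak.
#' @param next_threshold_index sample index of the next AP threshold, or `NA`.
#' @param v_rest burst resting potential, mV.
#' @param prev_threshold_value this AP's own threshold (the "previous AP
#'   threshold" for the repolarization that follows it), mV.
#' @param cap_ms search window after the AP when no next AP bounds it, ms.
#' @param min_band_points minimum samples in the 20-60% band for a slope.
#' @return list with `ahp_peak_index`, `ahp_peak_time`, `ahp_peak_value`,
#'   `amplitude`, `slope`, `duration`, `slope_flagged`.
#' @export
ahp_features <- function(trace, peak_index, next_threshold_index,
                         v_rest, prev_threshold_value, cap_ms = 300,
                         min_band_points = 3) {
  v <- trace$samples
  dt_ms <- 1000 / trace$fs
  cap <- round(cap_ms / dt_ms)
  i_end <- if (!is.na(next_threshold_index)) {
    min(next_threshold_index, peak_index + cap)
  } else min(peak_index + cap, length(v))
  if (i_end <= peak_index + 1)
    return(list(ahp_peak_index = NA_integer_, ahp_peak_time = NA_real_,
                ahp_peak_value = NA_real_, amplitude = NA_real_,
                slope = NA_real_, duration = NA_real_, slope_flagged = TRUE))
  win <- (peak_index + 1L):i_end
  i_ahp <- win[which.min(v[win])]
  ahp_val <- v[i_ahp]
  amplitude <- ahp_val - v_rest
  # 20-60% band from the AHP peak toward the previous AP threshold
  lo <- ahp_val + 0.2 * (prev_threshold_value - ahp_val)
  hi <- ahp_val + 0.6 * (prev_threshold_value - ahp_val)
  span <- i_ahp:i_end
  inb <- span[v[span] >= lo & v[span] <= hi]
  slope_flagged <- length(inb) < min_band_points
  slope <- if (!slope_flagged) {
    ix <- min(inb):max(inb)
    unname(fast_slope((ix - ix[1]) * dt_ms, v[ix])["slope"])
  } else NA_real_
  duration <- if (!is.na(next_threshold_index))
    (next_threshold_index - i_ahp) * dt_ms else NA_real_
  list(ahp_peak_index = i_ahp, ahp_peak_time = index_to_time(trace, i_ahp),
       ahp_peak_value = ahp_val, amplitude = amplitude, slope = slope,
       duration = duration, slope_flagged = slope_flagged)
}

#' Relative/normalized thresholds, intraburst frequency and burst size
#'
#' Relative threshold is `threshold - v_rest`; the normalized threshold
#' rescales it so that 0 is the resting potential and 1 the maximum of the
#' subthreshold fluctuations. Intraburst frequency is the mean of the inverse
#' ISIs within the burst.
#'
#' @param thresholds AP threshold values within the burst, mV.
#' @param isis intraburst inter-spike intervals, ms.
#' @param v_rest burst resting potential, mV.
#' @param fluct_amplitude maximum subthreshold Vm, mV.
#' @return list with `relative_thresholds`, `normalized_thresholds`,
#'   `intraburst_freq` (Hz), `size`, `normalized_flagged`.
#' @export
derived_burst_metrics <- function(thresholds, isis, v_rest,
                                  fluct_amplitude) {
  rel <- thresholds - v_rest
  denom <- fluct_amplitude - v_rest
  flagged <- !is.finite(denom) || denom == 0
  norm <- if (flagged) rep(NA_real_, length(rel)) else rel / denom
  freq <- if (length(isis)) mean(1000 / isis) else NA_real_
  list(relative_thresholds = rel, normalized_thresholds = norm,
       intraburst_freq = freq, size = length(thresholds),
       normalized_flagged = flagged)
}

#' Single-exponential least-squares fit
#'
#' Fits `v ~ v0 + A exp(-t/tau)` by profiling `tau` on a log grid (then
#' refining with golden-section search) and solving the linear pair
#' `(v0, A)` in closed form at each candidate. Deterministic; used for the
#' slow-AHP time constant.
#'
#' @param t_ms times, ms.
#' @param v voltages, mV.
#' @param tau_bounds search bounds for `tau`, ms.
#' @return list with `tau`, `v0`, `amplitude`, `sse`.
#' @export
fit_single_exp <- function(t_ms, v, tau_bounds = c(1, 5000)) {
  sse_for <- function(tau) {
    e <- exp(-t_ms / tau)
    cf <- fast_slope(e, v)
    r <- v - cf["intercept"] - cf["slope"] * e
    c(sum(r^2), cf["intercept"], cf["slope"])
  }
  taus <- exp(seq(log(tau_bounds[1]), log(tau_bounds[2]), length.out = 60))
  sses <- vapply(taus, function(tt) sse_for(tt)[1], numeric(1))
  tau0 <- taus[which.min(sses)]
  opt <- stats::optimize(function(tt) sse_for(tt)[1],
                         c(max(tau_bounds[1], tau0 / 3),
                           min(tau_bounds[2], tau0 * 3)))
  best <- sse_for(opt$minimum)
  list(tau = opt$minimum, v0 = unname(best[2]), amplitude = unname(best[3]),
       sse = unname(best[1]))
}

#' Slow-AHP time constant from post-burst median trace
#'
#' Selects bursts followed by an AP-free interval of at least
#' `min_interval_ms` (500 ms), aligns their post-burst segments on the AHP
#' peak following the last AP (nearest-sample alignment), computes a median
#' trace, and fits `v0 + A exp(-t/tau)` over the 50-500 ms window after the
#' AHP peak.
#'
#' @param trace a [vm_trace].
#' @param seg a `burst_segmentation`.
#' @param ap_table annotated AP table aligned with `seg$spike_times`.
#' @param v_rest_default fallback anchor (unused by the fit, kept for
#'   reporting).
#' @param min_interval_ms minimum post-burst silence, ms.
#' @param fit_window fit window after the AHP peak, ms.
#' @return list with `tau`, `amplitude`, `v0`, `n_bursts_used`,
#'   `available`; when no burst qualifies `available` is `FALSE` (in the
#'   recordings this happened in 7 of 49 cells).
#' @export
slow_ahp_tau <- function(trace, seg, ap_table, v_rest_default = NA,
                         min_interval_ms = 500, fit_window = c(50, 500)) {
  v <- trace$samples
  dt_ms <- 1000 / trace$fs
  # segments are aligned at full resolution, then sampled on a ~1 ms grid:
  # the slow component is smooth and this keeps the median cheap at 25 kHz
  dec <- max(1L, round(1 / dt_ms))
  n_seg <- round(fit_window[2] / dt_ms)
  segs <- list()
  for (k in seq_along(seg$bursts)) {
    last_ap <- seg$bursts[[k]][length(seg$bursts[[k]])]
    t_last <- seg$spike_times[last_ap]
    nxt <- seg$spike_times[seg$spike_times > t_last]
    interval <- if (length(nxt)) min(nxt) - t_last else
      index_to_time(trace, length(v)) - t_last
    if (interval < min_interval_ms) next
    i_peak0 <- ap_table$peak_index[last_ap]
    win <- (i_peak0 + 1L):min(i_peak0 + round(300 / dt_ms), length(v))
    i_ahp <- win[which.min(v[win])]
    if (i_ahp + n_seg > length(v)) next
    segs[[length(segs) + 1L]] <- v[seq(i_ahp, i_ahp + n_seg, by = dec)]
  }
  if (!length(segs))
    return(list(tau = NA_real_, amplitude = NA_real_, v0 = NA_real_,
                n_bursts_used = 0L, available = FALSE))
  med <- apply(do.call(rbind, segs), 2, stats::median)
  t_ms <- (seq_along(med) - 1) * dec * dt_ms
  sel <- which(t_ms >= fit_window[1] & t_ms <= fit_window[2])
  fit <- fit_single_exp(t_ms[sel], med[sel])
  list(tau = fit$tau, amplitude = fit$amplitude, v0 = fit$v0,
       n_bursts_used = length(segs), available = TRUE,
       median_trace = med, t_ms = t_ms)
}

#' Cell-level quality-control filter
#'
#' Applies the exclusion rules used for the recordings: fewer than
#' `min_bursts` (4) bursts, membrane resistance above `max_resistance_mohm`
#' (500 MOhm, not mitral-cell-like), no usable interburst interval for the
#' resting potential, or (for two-pulse evoked protocols) baselines
#' differing by more than `evoked_max_dv` (2 mV).
#'
#' @param cell_summaries data frame with columns `cell_id`, `n_bursts`, and
#'   optionally `resistance_mohm`, `has_rest_interval`, `evoked_baseline_dv`.
#' @param min_bursts minimum burst count.
#' @param max_resistance_mohm maximum membrane resistance, MOhm.
#' @param evoked_max_dv maximum baseline difference between evoked APs, mV.
#' @return list with `kept` (cell ids) and `dropped` (data frame `cell_id`,
#'   `reason`).
#' @export
qc_filter_cells <- function(cell_summaries, min_bursts = 4,
                            max_resistance_mohm = 500, evoked_max_dv = 2) {
  d <- cell_summaries
  reasons <- character(nrow(d))
  for (i in seq_len(nrow(d))) {
    r <- character()
    if (d$n_bursts[i] < min_bursts) r <- c(r, "too few bursts")
    if (!is.null(d$resistance_mohm) && is.finite(d$resistance_mohm[i]) &&
        d$resistance_mohm[i] > max_resistance_mohm)
      r <- c(r, "membrane resistance")
    if (!is.null(d$has_rest_interval) && !is.na(d$has_rest_interval[i]) &&
        !d$has_rest_interval[i])
      r <- c(r, "burst intervals too short")
    if (!is.null(d$evoked_baseline_dv) &&
        is.finite(d$evoked_baseline_dv[i]) &&
        d$evoked_baseline_dv[i] > evoked_max_dv)
      r <- c(r, "evoked baseline drift")
    reasons[i] <- paste(r, collapse = "; ")
  }
  list(kept = d$cell_id[reasons == ""],
       dropped = data.frame(cell_id = d$cell_id[reasons != ""],
                            reason = reasons[reasons != ""]))
}

#' Full feature extraction for one cell
#'
#' Chains spike detection, threshold localisation, adaptive burst
#' segmentation, burst contexts, pre-AP features, AHP features, derived
#' metrics and the slow-AHP fit into tidy per-AP and per-burst tables.
#'
#' @param trace a [vm_trace].
#' @param v_detect detection potential, mV.
#' @param min_isi minimum ISI, ms.
#' @param tisi0,mad_mult burst-recursion parameters.
#' @param threshold_method threshold criterion for [detect_ap_threshold].
#' @return list with `ap_table`, `burst_table`, `segmentation`, `slow_fit`.
#' @export
extract_cell_features <- function(trace, v_detect = -23, min_isi = 1,
                                  tisi0 = 90, mad_mult = 4,
                                  threshold_method = "second_derivative") {
  aps <- detect_aps(trace, v_detect, min_isi, method = threshold_method)
  seg <- detect_bursts_adaptive(aps$peak_time, tisi0, mad_mult)
  lab <- burst_labels(seg)
  aps$burst <- lab
  aps$index_in_burst <- NA_integer_
  for (k in seq_along(seg$bursts))
    aps$index_in_burst[seg$bursts[[k]]] <- seq_along(seg$bursts[[k]])

  # per-AP pre-AP and AHP features
  n_ap <- nrow(aps)
  pre <- vector("list", n_ap)
  ahp <- vector("list", n_ap)
  ctxs <- vector("list", length(seg$bursts))
  prev_ctx <- NULL
  for (k in seq_along(seg$bursts))
    prev_ctx <- ctxs[[k]] <- compute_burst_context(trace, seg, k, aps,
                                                   prev_context = prev_ctx)
  for (i in seq_len(n_ap)) {
    if (is.na(aps$threshold_index[i]) || aps$flagged[i]) next
    pre[[i]] <- pre_ap_features(trace, aps$threshold_index[i])
    k <- lab[i]
    vr <- if (!is.na(k)) ctxs[[k]]$v_rest else NA_real_
    nxt <- if (i < n_ap && !is.na(lab[i + 1]) && !is.na(k) &&
               lab[i + 1] == k) aps$threshold_index[i + 1] else NA_integer_
    ahp[[i]] <- ahp_features(trace, aps$peak_index[i], nxt,
                             v_rest = vr,
                             prev_threshold_value = aps$threshold_value[i])
  }
  getf <- function(lst, f) vapply(lst, function(x)
    if (is.null(x)) NA_real_ else as.numeric(x[[f]]), numeric(1))
  aps$pre_ap_value <- getf(pre, "pre_ap_value")
  aps$pre_ap_time <- getf(pre, "pre_ap_time")
  aps$pre_ap_slope <- getf(pre, "pre_ap_slope")
  aps$ahp_peak_time <- getf(ahp, "ahp_peak_time")
  aps$ahp_peak_value <- getf(ahp, "ahp_peak_value")
  aps$ahp_amplitude <- getf(ahp, "amplitude")
  aps$ahp_slope <- getf(ahp, "slope")
  aps$ahp_duration <- getf(ahp, "duration")
  aps$v_rest <- vapply(seq_len(n_ap), function(i)
    if (!is.na(lab[i])) ctxs[[lab[i]]]$v_rest %||% NA_real_ else NA_real_,
    numeric(1))

  burst_table <- do.call(rbind, lapply(seq_along(seg$bursts), function(k) {
    ix <- seg$bursts[[k]]
    ctx <- ctxs[[k]]
    isis <- diff(aps$threshold_time[ix])
    met <- derived_burst_metrics(aps$threshold_value[ix], isis,
                                 ctx$v_rest, ctx$fluct_amplitude)
    data.frame(cell_id = trace$cell_id, burst = k, size = met$size,
               v_rest = ctx$v_rest, fluct_amplitude = ctx$fluct_amplitude,
               inherited = isTRUE(ctx$inherited),
               excluded = isTRUE(ctx$excluded),
               intraburst_freq = met$intraburst_freq,
               first_threshold = aps$threshold_value[ix[1]],
               first_pre_ap = aps$pre_ap_value[ix[1]],
               first_pre_ap_slope = aps$pre_ap_slope[ix[1]],
               first_ahp_amplitude = aps$ahp_amplitude[ix[1]],
               first_ahp_slope = aps$ahp_slope[ix[1]],
               mean_rel_threshold = mean(met$relative_thresholds[-1]),
               mean_norm_threshold = mean(met$normalized_thresholds[-1]))
  }))
  if (is.null(burst_table))
    burst_table <- data.frame(cell_id = character(), burst = integer(),
                              size = integer())
  aps$cell_id <- trace$cell_id
  aps$relative_threshold <- aps$threshold_value - aps$v_rest
  slow <- slow_ahp_tau(trace, seg, aps)
  list(ap_table = aps, burst_table = burst_table, segmentation = seg,
       slow_fit = slow)
}
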
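#' Parameters for the synthetic mitral-cell recording generator
#'
#' Bundles the knobs of the ground-truth generator. Defaults emulate the
#' statistical structure of spontaneous mitral-cell recordings: resting
#' potential near -60 mV, subthreshold fluctuations of ~1.5 mV, bursts of
#' action potentials at tens of Hz separated by silent periods of more than
#' half a second, fast intraburst AHPs and a slow post-burst AHP component
#' with a time constant of 171.66 ms, and an AP threshold that hyperpolarizes
#' by 0.37 mV per mV of pre-AP hyperpolarization.
#'
#' `threshold_vs_preap_slope` is expressed as mV of threshold change per +1 mV
#' of pre-AP *hyperpolarization depth* (`v_rest - preAP`), so the default
#' -0.37 lowers the threshold when the membrane is hyperpolarized; the
#' regression of threshold on the pre-AP potential itself therefore has slope
#' +0.37.
#'
#' @param v_rest resting potential, mV.
#' @param fluct_amplitude peak of the subthreshold fluctuation above
#'   `v_rest`, mV.
#' @param fluct_freq fluctuation frequency, Hz. The recordings show fast
#'   interburst oscillations; the default is the canonical olfactory-bulb
#'   gamma frequency (40 Hz).
#' @param noise_sd SD of the additive AR(1) noise, mV.
#' @param n_bursts number of bursts to place.
#' @param burst_size_dist function(n) returning n burst sizes (AP counts,
#'   all >= 2).
#' @param intraburst_freq nominal intraburst firing rate, Hz.
#' @param threshold_base AP threshold when the pre-AP potential equals
#'   `v_rest`, mV.
#' @param threshold_vs_preap_slope threshold shift per mV of pre-AP
#'   hyperpolarization depth, mV/mV (negative).
#' @param threshold_noise_sd per-AP Gaussian scatter of the threshold
#'   around the linear law, mV (the recordings show substantial intrinsic
#'   threshold variability: within-cell R ~ 0.5).
#' @param ahp_amp fast-AHP trough relative to `v_rest`, mV (negative).
#' @param ahp_jitter per-spike SD of the AHP trough, mV.
#' @param tau_fast fast-AHP recovery time constant, ms.
#' @param tau_slow slow-AHP time constant, ms.
#' @param slow_buildup_rate rate at which the slow-AHP amplitude saturates
#'   with the number of APs in the burst (unitless per AP).
#' @param slow_amp_max asymptotic slow-AHP amplitude, mV (negative).
#' @param pre_dip_range range (mV) of the random pre-burst hyperpolarization
#'   depth that precedes each first AP.
#' @param gap_range range (ms) of interburst gaps (>= 500 ms so slow-AHP
#'   fitting is possible).
#' @param isi_jitter fractional SD of intraburst inter-spike intervals.
#' @param fs sampling frequency, Hz.
#' @param duration trace duration, s; `NULL` sizes the trace to fit the
#'   requested bursts.
#' @param seed integer RNG seed.
#' @return an object of class `generator_params`.
#' @export
generator_params <- function(v_rest = -60, fluct_amplitude = 1.5,
                             fluct_freq = 40, noise_sd = 0.1,
                             n_bursts = 10,
                             burst_size_dist = function(n) 2 + stats::rpois(n, 3),
                             intraburst_freq = 50,
                             threshold_base = -57,
                             threshold_vs_preap_slope = -0.37,
                             threshold_noise_sd = 0.3,
                             ahp_amp = -5, ahp_jitter = 0.3,
                             tau_fast = 8, tau_slow = 171.66,
                             slow_buildup_rate = 0.3, slow_amp_max = -3,
                             pre_dip_range = c(0.6, 3),
                             gap_range = c(550, 900),
                             isi_jitter = 0.08,
                             fs = 25000, duration = NULL, seed = 1) {
  p <- as.list(environment())
  if (p$fs <= 0) stop("fs must be > 0")
  if (p$ahp_amp >= 0) stop("ahp_amp must be negative")
  if (p$tau_fast >= p$tau_slow) stop("tau_fast must be < tau_slow")
  if (p$n_bursts < 0) stop("n_bursts must be >= 0")
  structure(p, class = "generator_params")
}

# stereotyped AP template: half-cosine rise (~0.3 ms) from threshold to
# +30 mV, half-cosine fall (~1 ms) to the AHP trough; shape is arbitrary,
# only downstream detectability matters
ap_template <- function(thr, trough, fs, peak = 30,
                        rise_ms = 0.3, fall_ms = 1.0) {
  nr <- max(3L, round(rise_ms * fs / 1000))
  nf <- max(5L, round(fall_ms * fs / 1000))
  up <- thr + (peak - thr) * (1 - cos(pi * (0:nr) / nr)) / 2
  dn <- peak + (trough - peak) * (1 - cos(pi * (1:nf) / nf)) / 2
  c(up, dn)  # index 1 = threshold sample, nr+1 = peak, nr+nf+1 = trough
}

#' Generate a synthetic mitral-cell recording with ground truth
#'
#' Builds a voltage trace containing `n_bursts` AP bursts on a fluctuating
#' subthreshold baseline. Each burst is preceded by a smooth hyperpolarizing
#' dip of random depth; the first-AP threshold is set from the realized
#' pre-AP minimum via `threshold_vs_preap_slope`, and each intraburst
#' threshold from the preceding AHP trough via the same law. Intraburst AHPs
#' recover exponentially with `tau_fast`; after the last AP a slow component
#' with `tau_slow` develops, its amplitude saturating with burst size.
#'
#' @param params a [generator_params] object.
#' @return list with elements `trace` (a [vm_trace]) and `truth` (list with
#'   `spikes` and `bursts` data frames and `tau_slow_true`).
#' @export
generate_cell_recording <- function(params) {
  stopifnot(inherits(params, "generator_params"))
  p <- params
  with_seed(p$seed, {
    dt_ms <- 1000 / p$fs
    nb <- p$n_bursts
    sizes <- if (nb > 0) pmax(2L, as.integer(p$burst_size_dist(nb))) else integer()
    gaps <- if (nb > 0) stats::runif(nb, p$gap_range[1], p$gap_range[2]) else numeric()
    dips <- if (nb > 0) stats::runif(nb, p$pre_dip_range[1], p$pre_dip_range[2]) else numeric()
    isi0 <- 1000 / p$intraburst_freq

    # schedule first-AP threshold times; bursts are separated by `gaps`
    isis <- vector("list", nb)
    t_first <- numeric(nb)
    cursor <- 100  # lead-in, ms
    for (k in seq_len(nb)) {
      t_first[k] <- cursor + gaps[k]
      ii <- if (sizes[k] > 1)
        isi0 * pmax(0.5, 1 + stats::rnorm(sizes[k] - 1, 0, p$isi_jitter))
      else numeric()
      isis[[k]] <- ii
      cursor <- t_first[k] + sum(ii)
    }
    end_ms <- if (nb > 0) cursor + 600 else 1000
    if (!is.null(p$duration)) {
      if (p$duration * 1000 < end_ms)
        stop(sprintf("bursts do not fit in duration: need >= %.2f s", end_ms / 1000))
      end_ms <- p$duration * 1000
    }
    n <- ceiling(end_ms / dt_ms)
    tms <- (seq_len(n) - 1) * dt_ms

    # baseline: zero-median sinusoid (median ~ v_rest, max ~ v_rest +
    # fluct_amplitude) with per-segment frequency jitter to decorrelate
    # phases across interburst intervals, plus AR(1) noise; zero median keeps
    # the across-burst median of post-burst segments unbiased
    seg_bounds <- unique(c(1L, if (nb > 0) round(t_first / dt_ms), n))
    freq_mult <- stats::runif(length(seg_bounds), 0.75, 1.25)
    phase <- numeric(n)
    ph <- stats::runif(1, 0, 2 * pi)
    for (s in seq_len(length(seg_bounds) - 1)) {
      idx <- seg_bounds[s]:(seg_bounds[s + 1])
      w <- 2 * pi * p$fluct_freq * freq_mult[s] / 1000
      phase[idx] <- ph + w * (tms[idx] - tms[idx[1]])
      ph <- phase[idx[length(idx)]]
    }
    fluct <- p$fluct_amplitude * sin(phase)
    phi <- exp(-dt_ms / 2)  # ~2 ms noise correlation time
    noise <- as.numeric(stats::filter(
      stats::rnorm(n, 0, p$noise_sd * sqrt(1 - phi^2)), phi,
      method = "recursive"))
    v <- p$v_rest + fluct + noise

    spike_rows <- list()
    burst_rows <- list()
    slope <- p$threshold_vs_preap_slope  # mV per mV hyperpolarization depth
    for (k in seq_len(nb)) {
      i_thr1 <- round(t_first[k] / dt_ms) + 1L
      # additive pre-burst dip over [-40, -8] ms, minimum ~8 ms before AP
      i_dip <- (i_thr1 - round(40 / dt_ms)):(i_thr1 - round(8 / dt_ms))
      s <- seq(0, 1, length.out = length(i_dip))
      v[i_dip] <- v[i_dip] - dips[k] * sin(pi * s)^2
      # provisional smooth rise from the window minimum toward the AP, then
      # locate the realized pre-AP potential with the same backward-rebound
      # rule the analyzer uses, so the threshold law is applied to exactly
      # the quantity the pipeline will measure
      win <- (i_thr1 - round(36 / dt_ms)):(i_thr1 - round(10 / dt_ms))
      i_pre0 <- win[which.min(v[win])]
      lay_rise <- function(end_value) {
        i_rise <- i_pre0:i_thr1  # includes the threshold sample itself
        s <- seq(0, 1, length.out = length(i_rise))
        v[i_rise] <<- v[i_pre0] + (end_value - v[i_pre0]) *
          (1 - cos(pi * s)) / 2
      }
      lay_rise(p$threshold_base)
      step <- max(1L, round(1 / dt_ms))
      i <- i_thr1
      repeat {
        i <- i - step
        if (i < i_thr1 - round(300 / dt_ms) || i < 1) break
        if (v[i] - min(v[i:i_thr1]) >= 0.4) break
      }
      segr <- max(1L, i):i_thr1
      i_pre <- segr[which.min(v[segr])]
      pre_ap <- v[i_pre]
      thr <- p$threshold_base - slope * (pre_ap - p$v_rest) +
        stats::rnorm(1, 0, p$threshold_noise_sd)
      lay_rise(thr)

      thr_times <- t_first[k] + c(0, cumsum(isis[[k]]))
      thr_idx <- round(thr_times / dt_ms) + 1L
      troughs <- p$v_rest + p$ahp_amp + stats::rnorm(sizes[k], 0, p$ahp_jitter)
      thrs <- numeric(sizes[k]); thrs[1] <- thr
      pre_aps <- numeric(sizes[k]); pre_aps[1] <- pre_ap
      pre_idx <- integer(sizes[k]); pre_idx[1] <- i_pre
      tr_idx <- integer(sizes[k])
      for (i in seq_len(sizes[k])) {
        if (i < sizes[k]) {
          # next AP's pre-AP potential is this AP's AHP trough
          pre_aps[i + 1] <- troughs[i]
          thrs[i + 1] <- p$threshold_base - slope * (troughs[i] - p$v_rest) +
            stats::rnorm(1, 0, p$threshold_noise_sd)
        }
        tpl <- ap_template(thrs[i], troughs[i], p$fs)
        ii <- thr_idx[i] + seq_along(tpl) - 1L
        v[ii] <- tpl
        tr_idx[i] <- ii[length(ii)]
        if (i > 1) pre_idx[i] <- tr_idx[i - 1]
        if (i < sizes[k]) {
          # exponential recovery ending exactly at the next threshold
          i0 <- tr_idx[i]; i1 <- thr_idx[i + 1] - 1L
          if (i1 > i0) {
            dtm <- (i1 + 1L - i0) * dt_ms
            e <- exp(-dtm / p$tau_fast)
            A <- (thrs[i + 1] - troughs[i] * e) / (1 - e)
            tt <- (seq(i0 + 1L, i1) - i0) * dt_ms
            v[seq(i0 + 1L, i1)] <- A + (troughs[i] - A) * exp(-tt / p$tau_fast)
          }
        }
      }
      # post-burst tail: fast + slow exponential components; the slow
      # amplitude saturates with burst size (buildup across the burst)
      a_slow <- p$slow_amp_max * (1 - exp(-p$slow_buildup_rate * sizes[k]))
      a_fast <- (troughs[sizes[k]] - p$v_rest) - a_slow
      i0 <- tr_idx[sizes[k]]
      i1 <- if (k < nb) round((t_first[k + 1] - 45) / dt_ms) else n
      idx <- i0:min(i1, n)
      tt <- (idx - i0) * dt_ms
      tail_v <- a_fast * exp(-tt / p$tau_fast) + a_slow * exp(-tt / p$tau_slow)
      # oscillations resume as the slow AHP itself decays: with a strong slow
      # component the early post-burst trace is clean, without one the
      # fluctuations are back immediately
      w <- 1 - min(1, abs(a_slow) / p$fluct_amplitude) * exp(-tt / p$tau_slow)
      v[idx] <- p$v_rest + tail_v + w * (fluct[idx] + noise[idx])

      spike_rows[[k]] <- data.frame(
        burst = k, index_in_burst = seq_len(sizes[k]),
        threshold_time = (thr_idx - 1) * dt_ms,
        threshold_value = thrs,
        peak_time = (thr_idx - 1) * dt_ms +
          (max(3L, round(0.3 * p$fs / 1000))) * dt_ms,
        pre_ap_time = (pre_idx - 1) * dt_ms,
        pre_ap_value = pre_aps,
        ahp_peak_time = (tr_idx - 1) * dt_ms,
        ahp_peak_value = troughs)
      burst_rows[[k]] <- data.frame(
        burst = k, size = sizes[k], first_threshold_time = t_first[k],
        v_rest = p$v_rest, pre_ap_value = pre_ap,
        slow_amp = a_slow)
    }
    spikes <- if (nb > 0) do.call(rbind, spike_rows) else
      data.frame(burst = integer(), index_in_burst = integer(),
                 threshold_time = numeric(), threshold_value = numeric(),
                 peak_time = numeric(), pre_ap_time = numeric(),
                 pre_ap_value = numeric(), ahp_peak_time = numeric(),
                 ahp_peak_value = numeric())
    bursts <- if (nb > 0) do.call(rbind, burst_rows) else
      data.frame(burst = integer(), size = integer(),
                 first_threshold_time = numeric(), v_rest = numeric(),
                 pre_ap_value = numeric(), slow_amp = numeric())
    list(trace = vm_trace(v, fs = p$fs,
                          cell_id = sprintf("synth-%d", p$seed)),
         truth = list(spikes = spikes, bursts = bursts,
                      tau_slow_true = p$tau_slow, v_rest = p$v_rest,
                      fluct_max = p$v_rest + p$fluct_amplitude))
  })
}

#' Generate a labelled spike train
#'
#' Construction fixture for burst-detection tests: bursts of given sizes with
#' given intraburst intervals and interburst gaps, optionally jittered.
#'
#' @param burst_sizes integer vector of AP counts (1 = isolated AP).
#' @param intraburst_isi intraburst inter-spike interval, ms.
#' @param gap interburst gap (last spike of one burst to first of the next),
#'   ms.
#' @param jitter_sd SD of Gaussian jitter added to the intraburst intervals,
#'   ms.
#' @param t0 time of the first spike, ms.
#' @param seed optional RNG seed (required if `jitter_sd > 0` for
#'   reproducibility).
#' @return list with `times` (ms, strictly increasing) and `labels` (integer
#'   burst index, `NA` for isolated single spikes).
#' @export
generate_spike_train <- function(burst_sizes, intraburst_isi = 10,
                                 gap = 1000, jitter_sd = 0, t0 = 0,
                                 seed = NULL) {
  if (gap <= intraburst_isi)
    stop("interburst gap must exceed the intraburst interval (bursts overlap)")
  gen <- function() {
    times <- numeric(0); labels <- integer(0); cursor <- t0
    for (k in seq_along(burst_sizes)) {
      sz <- burst_sizes[k]
      ii <- if (sz > 1) rep(intraburst_isi, sz - 1) else numeric()
      if (jitter_sd > 0 && sz > 1)
        ii <- pmax(intraburst_isi / 4, ii + stats::rnorm(sz - 1, 0, jitter_sd))
      tk <- cursor + c(0, cumsum(ii))
      times <- c(times, tk)
      labels <- c(labels, rep(if (sz >= 2) k else NA_integer_, sz))
      cursor <- tk[length(tk)] + gap
    }
    if (is.unsorted(times, strictly = TRUE)) stop("spike times not increasing")
    list(times = times, labels = labels)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Generate a noisy exponential AHP decay segment
#'
#' Fixture for slow-AHP fitting: `V(t) = v_rest + amplitude * exp(-t/tau) +
#' noise`.
#'
#' @param amplitude initial deviation from `v_rest`, mV (negative for an
#'   AHP).
#' @param tau decay time constant, ms (> 0).
#' @param noise_sd Gaussian noise SD, mV.
#' @param fs sampling frequency, Hz.
#' @param duration_ms segment length, ms.
#' @param v_rest baseline, mV.
#' @param seed optional RNG seed.
#' @return a [vm_trace]; the noiseless curve is attached as attribute
#'   `"clean"`.
#' @export
generate_ahp_decay <- function(amplitude, tau, noise_sd = 0, fs = 25000,
                               duration_ms = 600, v_rest = -60, seed = NULL) {
  if (!is.finite(tau) || tau <= 0) stop("tau must be > 0")
  gen <- function() {
    tms <- seq(0, duration_ms, by = 1000 / fs)
    clean <- v_rest + amplitude * exp(-tms / tau)
    v <- clean + if (noise_sd > 0) stats::rnorm(length(tms), 0, noise_sd) else 0
    tr <- vm_trace(v, fs = fs, cell_id = "ahp-decay")
    attr(tr, "clean") <- clean
    tr
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Write generator ground truth to JSON
#'
#' @param truth the `truth` element returned by [generate_cell_recording].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}
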
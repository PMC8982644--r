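# burst contexts -------------------------------------------------------

test_that("burst context: flat interval, inheritance, first-burst exclusion", {
  fs <- 25000
  # flat -60 mV for 500 ms, then a "burst" starting at 500 ms
  v <- rep(-60, 20000)
  tr <- vm_trace(v, fs = fs)
  seg <- structure(list(bursts = list(c(1L, 2L)), isolated = integer(),
                        final_tisi = 20, spike_times = c(500, 520)),
                   class = "burst_segmentation")
  aps <- data.frame(threshold_time = c(500, 520), cross_time = c(500, 520))
  ctx <- compute_burst_context(tr, seg, 1, aps)
  expect_equal(ctx$v_rest, -60)
  expect_equal(ctx$fluct_amplitude, -60)
  expect_false(ctx$inherited)

  # short preceding interval: inherit from the previous burst
  seg2 <- structure(list(bursts = list(c(1L, 2L), c(3L, 4L)),
                         isolated = integer(), final_tisi = 20,
                         spike_times = c(500, 520, 670, 690)),
                    class = "burst_segmentation")
  aps2 <- data.frame(threshold_time = c(500, 520, 670, 690),
                     cross_time = c(500, 520, 670, 690))
  prev <- compute_burst_context(tr, seg2, 1, aps2)
  ctx2 <- compute_burst_context(tr, seg2, 2, aps2, prev_context = prev)
  expect_true(ctx2$inherited)
  expect_equal(ctx2$v_rest, prev$v_rest)
  # first burst with a short interval and no predecessor -> excluded
  seg3 <- structure(list(bursts = list(c(1L, 2L)), isolated = integer(),
                         final_tisi = 20, spike_times = c(100, 120)),
                    class = "burst_segmentation")
  aps3 <- data.frame(threshold_time = c(100, 120), cross_time = c(100, 120))
  ctx3 <- compute_burst_context(tr, seg3, 1, aps3)
  expect_true(ctx3$excluded)
})

test_that("burst context picks up a sinusoidal excursion", {
  fs <- 25000
  tms <- (0:(20000 - 1)) / fs * 1000
  v <- -60 + 2 * pmax(0, sin(2 * pi * (tms - 100) / 200)) * (tms > 100 & tms < 200)
  tr <- vm_trace(v, fs = fs)
  seg <- structure(list(bursts = list(1L:2L), isolated = integer(),
                        final_tisi = 20, spike_times = c(600, 620)),
                   class = "burst_segmentation")
  aps <- data.frame(threshold_time = c(600, 620), cross_time = c(600, 620))
  ctx <- compute_burst_context(tr, seg, 1, aps)
  expect_equal(ctx$fluct_amplitude - ctx$v_rest, 2, tolerance = 0.05)
})

# pre-AP features ------------------------------------------------------

test_that("pre-AP dip is located exactly; 0.4 mV rebound is accepted", {
  fs <- 25000
  v <- rep(-60, 10000)
  # V-shaped dip 3 ms before "threshold" at sample 6000, 1 mV rebound
  thr_i <- 6000L
  dip_i <- thr_i - 75L   # 3 ms
  v[(dip_i - 50):dip_i] <- seq(-60, -62, length.out = 51)
  v[dip_i:thr_i] <- seq(-62, -58, length.out = thr_i - dip_i + 1)
  tr <- vm_trace(v, fs = fs)
  pre <- pre_ap_features(tr, thr_i)
  expect_equal(pre$pre_ap_index, dip_i)
  expect_equal(pre$pre_ap_value, -62)
  expect_false(pre$flagged)

  # rebound of exactly 0.4 mV still stops the backward search ("at least")
  v2 <- rep(-60, 10000)
  v2[(dip_i - 50):dip_i] <- seq(-60.4, -61, length.out = 51)
  v2[dip_i:thr_i] <- seq(-61, -58, length.out = thr_i - dip_i + 1)
  pre2 <- pre_ap_features(vm_trace(v2, fs = fs), thr_i)
  expect_false(pre2$flagged)
  expect_equal(pre2$pre_ap_value, -61)
})

test_that("pre-AP slope equals the ramp slope for a linear approach", {
  fs <- 25000
  v <- rep(-60, 10000)
  thr_i <- 6000L
  dip_i <- thr_i - 250L  # 10 ms before threshold (> 5 ms branch)
  s <- 0.35  # mV/ms
  v[(dip_i - 100):dip_i] <- seq(-59, -62.5, length.out = 101)
  ramp_t <- (0:(thr_i - dip_i)) / fs * 1000
  v[dip_i:thr_i] <- -62.5 + s * ramp_t
  pre <- pre_ap_features(vm_trace(v, fs = fs), thr_i)
  expect_equal(pre$pre_ap_slope, s, tolerance = 1e-6)

  # flagged when no rebound exists within the lookback
  vflat <- rep(-60, 10000)
  pref <- pre_ap_features(vm_trace(vflat, fs = fs), 9000L)
  expect_true(pref$flagged)
})

# AHP features ---------------------------------------------------------

test_that("AHP amplitude, slope, duration and the 300 ms cap", {
  fs <- 25000
  dt <- 1000 / fs
  v <- rep(-60, 30000)
  peak_i <- 1000L
  # trough -65 at peak_i + 50; linear recovery at rate r to the next
  # threshold (-50) reached 15 ms later
  v[peak_i:(peak_i + 50)] <- seq(30, -65, length.out = 51)
  r <- 1.0  # mV/ms
  rec_n <- 15 / dt
  v[(peak_i + 50):(peak_i + 50 + rec_n)] <- -65 + r * (0:rec_n) * dt
  nxt <- as.integer(peak_i + 50 + rec_n)
  f <- ahp_features(vm_trace(v, fs = fs), peak_i, nxt, v_rest = -60,
                    prev_threshold_value = -50)
  expect_equal(f$ahp_peak_value, -65)
  expect_equal(f$amplitude, -5)       # -65 - (-60)
  expect_equal(f$slope, r, tolerance = 1e-6)  # linear: slope = r in any band
  expect_equal(f$duration, (nxt - (peak_i + 50)) * dt)

  # long ISI: search window capped at 300 ms after the AP
  v2 <- rep(-60, 30000)
  v2[peak_i] <- 30
  v2[peak_i + round(320 / dt)] <- -70   # minimum beyond the cap: ignored
  v2[peak_i + round(100 / dt)] <- -64
  f2 <- ahp_features(vm_trace(v2, fs = fs), peak_i, NA_integer_,
                     v_rest = -60, prev_threshold_value = -50)
  expect_equal(f2$ahp_peak_value, -64)
  expect_true(is.na(f2$duration))
})

# derived metrics ------------------------------------------------------

test_that("normalized threshold anchors and intraburst frequency", {
  m <- derived_burst_metrics(thresholds = c(-60, -58.5), isis = c(10, 20),
                             v_rest = -60, fluct_amplitude = -58.5)
  expect_equal(m$normalized_thresholds, c(0, 1))
  expect_equal(m$intraburst_freq, (100 + 50) / 2)
  expect_equal(m$size, 2)
  # thresholds below rest -> normalized < 0
  m2 <- derived_burst_metrics(c(-61), numeric(0), -60, -58.5)
  expect_lt(m2$normalized_thresholds, 0)
  # degenerate denominator flagged
  m3 <- derived_burst_metrics(c(-59), numeric(0), -60, -60)
  expect_true(m3$normalized_flagged)
})

# slow AHP -------------------------------------------------------------

test_that("slow-AHP fit recovers a noiseless exponential exactly", {
  tr <- generate_ahp_decay(-4, tau = 150, noise_sd = 0, duration_ms = 600)
  fit <- fit_single_exp(trace_times(tr)[trace_times(tr) >= 50 &
                                          trace_times(tr) <= 500],
                        tr$samples[trace_times(tr) >= 50 &
                                     trace_times(tr) <= 500])
  expect_equal(fit$tau, 150, tolerance = 1e-4)
  expect_equal(fit$v0, -60, tolerance = 1e-6)
})

test_that("slow-AHP unavailable when no burst has >= 500 ms of silence", {
  cc <- cached_cell()
  seg <- cc$feats$segmentation
  # shrink the qualifying interval requirement artificially high instead of
  # regenerating: no burst has 10 s of silence
  out <- slow_ahp_tau(cc$rec$trace, seg, cc$feats$ap_table,
                      min_interval_ms = 1e4)
  expect_false(out$available)
  expect_equal(out$n_bursts_used, 0)
})

test_that("round trip: features match generator ground truth", {
  cc <- cached_cell()
  ts <- cc$rec$truth$spikes
  a <- cc$feats$ap_table
  first <- ts$index_in_burst == 1
  expect_lt(max(abs(a$pre_ap_value[first] - ts$pre_ap_value[first])), 0.2)
  # AHP peaks within 1 sample / exact value for intraburst APs
  not_last <- ts$index_in_burst < ave(ts$index_in_burst, ts$burst, FUN = max)
  expect_lt(max(abs(a$ahp_peak_time[not_last] - ts$ahp_peak_time[not_last])),
            2 * 1000 / 25000)
  expect_equal(a$v_rest[!is.na(a$v_rest)],
               rep(-60, sum(!is.na(a$v_rest))), tolerance = 0.5)
  expect_equal(cc$feats$slow_fit$tau, 171.66, tolerance = 0.1)
})

test_that("features are invariant to a constant trace offset", {
  cc <- cached_cell()
  tr2 <- cc$rec$trace
  tr2$samples <- tr2$samples + 5
  f2 <- extract_cell_features(tr2, v_detect = -23 + 5)
  a1 <- cc$feats$ap_table; a2 <- f2$ap_table
  expect_equal(nrow(a1), nrow(a2))
  expect_equal(a2$ahp_amplitude, a1$ahp_amplitude, tolerance = 1e-6)
  expect_equal(a2$ahp_slope, a1$ahp_slope, tolerance = 1e-6)
  expect_equal(a2$ahp_duration, a1$ahp_duration, tolerance = 1e-6)
  expect_equal(a2$relative_threshold, a1$relative_threshold,
               tolerance = 1e-6)
  b1 <- cc$feats$burst_table; b2 <- f2$burst_table
  expect_equal(b2$mean_norm_threshold, b1$mean_norm_threshold,
               tolerance = 1e-5)
})

test_that("AHP amplitude is negative when the minimum is below rest", {
  cc <- cached_cell()
  a <- cc$feats$ap_table
  ok <- !is.na(a$ahp_amplitude) & !is.na(a$ahp_peak_value) & !is.na(a$v_rest)
  below <- ok & (a$ahp_peak_value < a$v_rest)
  expect_true(all(a$ahp_amplitude[below] < 0))
})

# QC -------------------------------------------------------------------

test_that("cell QC applies the exclusion rules with reasons", {
  d <- data.frame(cell_id = c("a", "b", "c", "d"),
                  n_bursts = c(3, 10, 10, 10),
                  resistance_mohm = c(NA, 600, NA, 100),
                  has_rest_interval = c(TRUE, TRUE, FALSE, TRUE))
  qc <- qc_filter_cells(d)
  expect_equal(qc$kept, "d")
  expect_match(qc$dropped$reason[qc$dropped$cell_id == "a"], "too few bursts")
  expect_match(qc$dropped$reason[qc$dropped$cell_id == "b"], "resistance")
  expect_match(qc$dropped$reason[qc$dropped$cell_id == "c"], "too short")
})
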
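# shared fixtures built in code

flat_trace <- function(v = -60, ms = 1000, fs = 25000)
  vm_trace(rep(v, round(ms * fs / 1000)), fs = fs)

# one artificial AP on a flat baseline: linear approach, then quadratic
# onset at a known sample (analytic second-derivative oracle)
quadratic_onset_trace <- function(fs = 25000, v0 = -60, k_onset = 5000,
                                  accel = 5) {
  n <- 10000
  v <- rep(v0, n)
  ramp <- 1:1000
  v[k_onset - 1000 + ramp] <- v0 + 0.0005 * ramp   # gentle linear approach
  t_ms <- (1:(n - k_onset)) * 1000 / fs
  v[(k_onset + 1):n] <- v[k_onset] + accel * t_ms^2  # strictly positive d2
  v <- pmin(v, 30)
  list(trace = vm_trace(v, fs = fs), onset_index = k_onset + 1L)
}

# small cohort cached across tests (generation is the expensive part)
.cohort_cache <- new.env()
cached_cell <- function(seed = 42, n_bursts = 10) {
  key <- paste0("s", seed, "n", n_bursts)
  if (is.null(.cohort_cache[[key]])) {
    rec <- generate_cell_recording(generator_params(seed = seed,
                                                    n_bursts = n_bursts))
    feats <- extract_cell_features(rec$trace)
    .cohort_cache[[key]] <- list(rec = rec, feats = feats)
  }
  .cohort_cache[[key]]
}

base_model_cached <- function(ia_variant = "original") {
  key <- paste0("cfg_", ia_variant)
  if (is.null(.cohort_cache[[key]])) {
    cfg <- model_config(ia_variant = ia_variant)
    if (ia_variant != "original")
      cfg$holding_pa <- find_holding_current(cfg)$pa
    .cohort_cache[[key]] <- cfg
  }
  .cohort_cache[[key]]
}
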
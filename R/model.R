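.kin_cache <- new.env(parent = emptyenv())

boltzmann <- function(v, vh, k) 1 / (1 + exp(-(v - vh) / k))

#' Channel kinetics of the single-compartment model
#'
#' Loads the gating parameterization shipped in
#' `inst/extdata/kinetics.json` (the single place where the rate constants
#' are pinned) and returns the steady-state and time-constant functions for
#' the requested A-type variant. The modified A-type inactivation differs
#' from the original in its half-inactivation (-90 instead of -110 mV),
#' inactivation-curve slope (0.1 instead of 0.056 per mV) and inactivation
#' time constant (50 instead of 150 ms).
#'
#' @param ia_variant `"original"`, `"modified"` or `"none"`.
#' @return list of functions `minf, tau_m, hinf, tau_h, ninf, tau_n, ainf,
#'   tau_a, binf, tau_b` plus the raw parameter list as `$params`.
#' @export
channel_kinetics <- function(ia_variant = c("original", "modified", "none")) {
  ia_variant <- match.arg(ia_variant)
  if (is.null(.kin_cache$params)) {
    path <- system.file("extdata", "kinetics.json", package = "ahpburst")
    if (path == "") path <- file.path("inst", "extdata", "kinetics.json")
    .kin_cache$params <- jsonlite::read_json(path, simplifyVector = TRUE)
  }
  p <- .kin_cache$params
  gate <- function(g) {
    force(g)
    list(inf = function(v) boltzmann(v, g$vh, g$k),
         tau = if (!is.null(g$tau_const)) {
           function(v) rep(g$tau_const, length(v))
         } else {
           function(v) g$tau_base + g$tau_amp *
             exp(-((v - g$tau_vmid) / g$tau_width)^2)
         })
  }
  m <- gate(p$nav$m); h <- gate(p$nav$h); n <- gate(p$kdr$n); a <- gate(p$ia$a)
  bpar <- if (ia_variant == "modified") p$ia$b_modified else p$ia$b_original
  bt <- p$ia$b_tau
  binf <- function(v) 1 / (1 + exp((v - bpar$vh) * bpar$slope_per_mv))
  tau_b <- function(v) bpar$tau_inact *
    (bt$rec_frac + (1 - bt$rec_frac) * boltzmann(v, bt$tau_vmid, bt$tau_k))
  list(minf = m$inf, tau_m = m$tau, hinf = h$inf, tau_h = h$tau,
       ninf = n$inf, tau_n = n$tau, ainf = a$inf, tau_a = a$tau,
       binf = binf, tau_b = tau_b, m_exp = p$nav$m$exponent,
       cm = p$cm_uf_cm2, params = p, ia_variant = ia_variant)
}

#' Configuration of the single-compartment conductance-based model
#'
#' Defaults are the printed base model: conductance densities 0.02, 0.0002,
#' 0.003 and 3.33e-5 S/cm2 for Nav, delayed-rectifier K, A-type K and
#' passive; reversal potentials +90, -91 and -28.878 mV; 0.1 ms time steps;
#' nominal temperature 30 C (no additional q10 scaling is applied beyond
#' what the kinetics embed). With these values the model rests at -60 mV
#' without holding current. The membrane area (which only scales absolute
#' currents, never voltages) defaults to a 30-um-diameter spherical soma.
#'
#' @param g_nav,g_kdr,g_ia,g_pas conductance densities, S/cm2.
#' @param e_na,e_k,e_pas reversal potentials, mV.
#' @param dt integration step, ms.
#' @param membrane_area compartment area, cm2.
#' @param holding_pa constant injected holding current, pA.
#' @param ia_variant `"original"`, `"modified"` or `"none"`.
#' @param temperature nominal temperature, degrees C (metadata).
#' @param v_init initial voltage, mV (gates start at steady state there).
#' @return object of class `model_config`.
#' @export
model_config <- function(g_nav = 0.02, g_kdr = 2e-4, g_ia = 3e-3,
                         g_pas = 3.33e-5, e_na = 90, e_k = -91,
                         e_pas = -28.878, dt = 0.1,
                         membrane_area = pi * (30e-4)^2,
                         holding_pa = 0,
                         ia_variant = c("original", "modified", "none"),
                         temperature = 30, v_init = -60) {
  ia_variant <- match.arg(ia_variant)
  if (any(c(g_nav, g_kdr, g_ia, g_pas) < 0)) stop("conductances must be >= 0")
  if (dt <= 0) stop("dt must be > 0")
  if (ia_variant == "none") g_ia <- 0
  structure(list(g_nav = g_nav, g_kdr = g_kdr, g_ia = g_ia, g_pas = g_pas,
                 e_na = e_na, e_k = e_k, e_pas = e_pas, dt = dt,
                 membrane_area = membrane_area, holding_pa = holding_pa,
                 ia_variant = ia_variant, temperature = temperature,
                 v_init = v_init,
                 kinetics = channel_kinetics(ia_variant)),
            class = "model_config")
}

#' Current-clamp protocol builders
#'
#' `protocol_steps` builds an epoch table from amplitudes (pA) and durations
#' (ms); `protocol_pulse_train` builds the 40 Hz train protocol (square
#' pulses of `amp_pa` and `width_ms` at `rate_hz`); `protocol_prehyp` builds
#' the two-phase protocol of a hyperpolarizing pre-step followed by a short
#' suprathreshold step.
#'
#' @param amp_pa,dur_ms epoch amplitudes (pA) and durations (ms).
#' @return data frame with columns `amp_pa`, `dur_ms`.
#' @export
protocol_steps <- function(amp_pa, dur_ms) {
  if (any(dur_ms <= 0)) stop("durations must be > 0")
  data.frame(amp_pa = amp_pa, dur_ms = dur_ms)
}

#' @rdname protocol_steps
#' @param n_pulses,rate_hz,width_ms,lead_ms,post_ms train shape.
#' @export
protocol_pulse_train <- function(n_pulses, rate_hz = 40, amp_pa = 1000,
                                 width_ms = 3, lead_ms = 200,
                                 post_ms = 600) {
  period <- 1000 / rate_hz
  gap <- period - width_ms
  if (gap <= 0) stop("pulse width exceeds the train period")
  amps <- c(0, rep(c(amp_pa, 0), n_pulses))
  durs <- c(lead_ms, rep(c(width_ms, gap), n_pulses))
  durs[length(durs)] <- post_ms
  protocol_steps(amps, durs)
}

#' @rdname protocol_steps
#' @param pre_pa,pre_ms pre-step amplitude (pA) and duration (ms).
#' @param step_pa,step_ms test-pulse amplitude (pA) and duration (ms).
#' @export
protocol_prehyp <- function(pre_pa, pre_ms = 50, step_pa = 400,
                            step_ms = 3, lead_ms = 200, post_ms = 30) {
  protocol_steps(c(0, pre_pa, step_pa, 0),
                 c(lead_ms, pre_ms, step_ms, post_ms))
}

# core fixed-step integrator: exponential (cnexp-style) voltage update --
# exact for conductances frozen over the step, hence exact in the passive
# limit -- and exponential-Euler gates; unconditionally stable at 0.1 ms
integrate_cc <- function(config, i_pa, state = NULL) {
  k <- config$kinetics
  dt <- config$dt
  n <- length(i_pa)
  v <- numeric(n)
  gm <- gh <- gn <- ga <- gb <- numeric(n)
  ina <- ik <- ia <- numeric(n)
  v0 <- config$v_init
  if (is.null(state)) {
    state <- list(v = v0, m = k$minf(v0), h = k$hinf(v0), n = k$ninf(v0),
                  a = k$ainf(v0), b = k$binf(v0))
  }
  vv <- state$v; m <- state$m; h <- state$h; nn <- state$n
  a <- state$a; b <- state$b
  i_dens <- (i_pa + config$holding_pa) * 1e-9 / config$membrane_area # mA/cm2
  cfac <- 1000 / k$cm
  m_exp <- k$m_exp
  g_nav <- config$g_nav; g_kdr <- config$g_kdr; g_ia <- config$g_ia
  g_pas <- config$g_pas
  e_na <- config$e_na; e_k <- config$e_k; e_pas <- config$e_pas
  minf <- k$minf; tau_m <- k$tau_m; hinf <- k$hinf; tau_h <- k$tau_h
  ninf <- k$ninf; tau_n <- k$tau_n; ainf <- k$ainf; tau_a <- k$tau_a
  binf <- k$binf; tau_b <- k$tau_b
  hdt <- dt / 2
  for (t in seq_len(n)) {
    # Strang splitting: half-step exponential-Euler gate update at the old
    # voltage, full-step exponential voltage update (exact for frozen
    # conductances), half-step gate update at the new voltage -- second
    # order, unconditionally stable
    m <- m + (minf(vv) - m) * (1 - exp(-hdt / tau_m(vv)))
    h <- h + (hinf(vv) - h) * (1 - exp(-hdt / tau_h(vv)))
    nn <- nn + (ninf(vv) - nn) * (1 - exp(-hdt / tau_n(vv)))
    a <- a + (ainf(vv) - a) * (1 - exp(-hdt / tau_a(vv)))
    b <- b + (binf(vv) - b) * (1 - exp(-hdt / tau_b(vv)))
    gna <- g_nav * m^m_exp * h
    gk <- g_kdr * nn
    gia <- g_ia * a * b
    gtot <- gna + gk + gia + g_pas
    v_inf <- (gna * e_na + (gk + gia) * e_k + g_pas * e_pas + i_dens[t]) / gtot
    vv <- v_inf + (vv - v_inf) * exp(-dt * cfac * gtot)
    m <- m + (minf(vv) - m) * (1 - exp(-hdt / tau_m(vv)))
    h <- h + (hinf(vv) - h) * (1 - exp(-hdt / tau_h(vv)))
    nn <- nn + (ninf(vv) - nn) * (1 - exp(-hdt / tau_n(vv)))
    a <- a + (ainf(vv) - a) * (1 - exp(-hdt / tau_a(vv)))
    b <- b + (binf(vv) - b) * (1 - exp(-hdt / tau_b(vv)))
    gna <- g_nav * m^m_exp * h
    gk <- g_kdr * nn
    gia <- g_ia * a * b
    v[t] <- vv
    gm[t] <- m; gh[t] <- h; gn[t] <- nn; ga[t] <- a; gb[t] <- b
    ina[t] <- gna * (vv - config$e_na)
    ik[t] <- gk * (vv - config$e_k)
    ia[t] <- gia * (vv - config$e_k)
  }
  if (any(!is.finite(v)) || max(abs(v)) > 500)
    stop(sprintf("numerical divergence (|Vm| reached %.1f mV); check dt/config",
                 max(abs(v[is.finite(v)]), 0)))
  list(v = v, gates = data.frame(m = gm, h = gh, n = gn, a = ga, b = gb),
       currents = data.frame(i_na = ina, i_kdr = ik, i_ia = ia),
       state = list(v = vv, m = m, h = h, n = nn, a = a, b = b))
}

#' Simulate the model in current clamp
#'
#' Fixed-step integration (implicit-Euler voltage, exponential-Euler gates)
#' of the single-compartment membrane equation under an epoch-wise constant
#' injected current. Deterministic.
#'
#' @param config a [model_config].
#' @param protocol epoch table from [protocol_steps] and friends.
#' @param settle_ms equilibration time simulated before the protocol (with
#'   zero protocol current but including the holding current), ms.
#' @return list of class `cc_sim`: `trace` (a [vm_trace], fs = 1000/dt kHz),
#'   `gates` (data frame of gating variables over time), `currents`
#'   (densities, mA/cm2), `i_pa` (injected protocol current), `config`.
#' @export
simulate_current_clamp <- function(config, protocol, settle_ms = 500) {
  dt <- config$dt
  i_pa <- c(rep(0, round(settle_ms / dt)),
            unlist(Map(function(a, d) rep(a, round(d / dt)),
                       protocol$amp_pa, protocol$dur_ms)))
  res <- integrate_cc(config, i_pa)
  structure(list(trace = vm_trace(res$v, fs = 1000 / dt,
                                  cell_id = "model"),
                 gates = res$gates, currents = res$currents,
                 i_pa = i_pa, settle_ms = settle_ms, config = config,
                 state = res$state),
            class = "cc_sim")
}

#' Steady-state membrane current at a clamped voltage
#'
#' Algebraic net membrane current density with all gates at their
#' steady-state values -- the independent oracle for holding-current and
#' resting-state computations (zero net current at a stable voltage means
#' the model rests there).
#'
#' @param config a [model_config].
#' @param v voltage, mV.
#' @param include_holding subtract the configured holding current?
#' @return net current density, mA/cm2 (positive = outward).
#' @export
steady_state_current <- function(config, v, include_holding = TRUE) {
  k <- config$kinetics
  i <- config$g_nav * k$minf(v)^k$m_exp * k$hinf(v) * (v - config$e_na) +
    config$g_kdr * k$ninf(v) * (v - config$e_k) +
    config$g_ia * k$ainf(v) * k$binf(v) * (v - config$e_k) +
    config$g_pas * (v - config$e_pas)
  if (include_holding)
    i <- i - config$holding_pa * 1e-9 / config$membrane_area
  i
}

#' Holding current required to rest at a target voltage
#'
#' Root-finds (bisection via `uniroot`) the constant injected current for
#' which the simulated steady-state voltage equals `target_v`. The
#' simulation-based root is cross-checkable against
#' [steady_state_current].
#'
#' @param config a [model_config].
#' @param target_v target resting potential, mV.
#' @param bracket_pa search interval, pA.
#' @param settle_ms settle time per evaluation, ms.
#' @return list with `pa` (absolute current, pA) and `pa_per_cm2` (density,
#'   pA/cm2).
#' @export
find_holding_current <- function(config, target_v = -60,
                                 bracket_pa = c(-150, 100),
                                 settle_ms = 800) {
  f <- function(i) {
    cfg <- config; cfg$holding_pa <- i; cfg$v_init <- target_v
    res <- integrate_cc(cfg, rep(0, round(settle_ms / cfg$dt)))
    res$state$v - target_v
  }
  lo <- f(bracket_pa[1]); hi <- f(bracket_pa[2])
  if (sign(lo) == sign(hi))
    stop("no bracketing interval for the holding current; widen bracket_pa")
  root <- stats::uniroot(f, bracket_pa, f.lower = lo, f.upper = hi,
                         tol = 1e-4)$root
  list(pa = root, pa_per_cm2 = root / config$membrane_area)
}

#' Spike threshold of a model trace by the dV/dt criterion
#'
#' The threshold is the voltage at which dV/dt first exceeds `dvdt_cut`
#' (40 mV/ms). The crossing is located with sub-sample linear interpolation:
#' at 0.1 ms steps the voltage advances ~4 mV per sample at the cut, so the
#' raw first supra-cut sample would quantize the threshold unacceptably.
#'
#' @param trace a [vm_trace] (or a `cc_sim`, whose trace is used).
#' @param dvdt_cut rate criterion, mV/ms.
#' @param from_ms restrict the search to times at or after this, ms.
#' @return list with `threshold` (mV) and `time` (ms), or both `NA` when no
#'   spike crosses the criterion.
#' @export
measure_model_threshold <- function(trace, dvdt_cut = 40, from_ms = 0) {
  if (inherits(trace, "cc_sim")) trace <- trace$trace
  v <- trace$samples
  dt_ms <- 1000 / trace$fs
  dv <- diff(v) / dt_ms
  from <- max(1L, round(from_ms / dt_ms))
  i <- which(dv > dvdt_cut & seq_along(dv) >= from)[1]
  if (is.na(i) || i < 2)
    return(list(threshold = NA_real_, time = NA_real_))
  # dv[j] estimates dV/dt at the midpoint between samples j and j+1; locate
  # the crossing on that midpoint grid, then interpolate V there
  f <- (dvdt_cut - dv[i - 1]) / (dv[i] - dv[i - 1])
  f <- max(0, min(1, f))
  pos <- (i - 1) + 0.5 + f          # fractional sample index (1-based)
  j <- floor(pos)
  w <- pos - j
  list(threshold = v[j] * (1 - w) + v[min(j + 1, length(v))] * w,
       time = index_to_time(trace, 1) + (pos - 1) * dt_ms)
}

#' AP threshold versus pre-AP membrane potential
#'
#' For each requested pre-AP level, root-finds the 50 ms hyperpolarizing
#' pre-step amplitude that lands the membrane at that level, delivers the
#' test pulse, and measures the threshold by the dV/dt criterion. Returns
#' the per-level thresholds and the linear slope of threshold versus pre-AP
#' potential (mV/mV).
#'
#' @param config a [model_config] (holding current should already place the
#'   model at -60 mV).
#' @param prehyp_levels target pre-AP potentials, mV.
#' @param pre_ms pre-step duration, ms.
#' @param step_pa,step_ms test pulse.
#' @return list with `curve` (data frame `target`, `pre_v`, `threshold`,
#'   `flagged`) and `slope`.
#' @export
threshold_shift_curve <- function(config, prehyp_levels = c(-60, -62.5, -65,
                                                            -67.5, -70),
                                  pre_ms = 50, step_pa = 400, step_ms = 3) {
  dt <- config$dt
  lead <- 200
  pre_n <- round(pre_ms / dt)
  run <- function(pre_pa) {
    sim <- simulate_current_clamp(
      config, protocol_steps(c(0, pre_pa, step_pa, 0),
                             c(lead, pre_ms, step_ms, 30)),
      settle_ms = 300)
    i_pre_end <- round((300 + lead + pre_ms) / dt)
    list(pre_v = sim$trace$samples[i_pre_end],
         thr = measure_model_threshold(
           sim, from_ms = (300 + lead + pre_ms))$threshold)
  }
  rows <- lapply(prehyp_levels, function(tv) {
    pa <- if (abs(tv - (-60)) < 1e-9) 0 else {
      tryCatch(stats::uniroot(function(p) run(p)$pre_v - tv,
                              c(-80, 10), tol = 1e-3)$root,
               error = function(e) NA_real_)
    }
    if (is.na(pa))
      return(data.frame(target = tv, pre_v = NA_real_,
                        threshold = NA_real_, flagged = TRUE))
    r <- run(pa)
    data.frame(target = tv, pre_v = r$pre_v, threshold = r$thr,
               flagged = is.na(r$thr))
  })
  curve <- do.call(rbind, rows)
  ok <- !curve$flagged
  slope <- if (sum(ok) >= 2)
    unname(stats::coef(stats::lm(threshold ~ pre_v, curve[ok, ]))[2])
  else NA_real_
  list(curve = curve, slope = slope)
}

#' Activatable (non-inactivated) Nav conductance
#'
#' The fraction of non-inactivated Nav conductance just before a stimulus
#' (the h gate) times the total Nav density.
#'
#' @param config a [model_config].
#' @param h h-gate value just before the stimulus (e.g. from a `cc_sim`'s
#'   `gates`).
#' @return available conductance density, S/cm2.
#' @export
activatable_nav <- function(config, h) config$g_nav * h

#' AP threshold versus activatable Nav conductance
#'
#' Varies the Nav density over `g_values` (0.04 down to 0.0025 S/cm2), holds
#' each model at -60 mV, elicits one spike from rest, and measures the
#' threshold and the activatable conductance just before the pulse.
#'
#' @param config template [model_config] (its `g_nav` is overridden).
#' @param g_values Nav densities to test, S/cm2.
#' @param step_pa,step_ms test pulse.
#' @return data frame `g_nav`, `activatable`, `threshold`, `holding_pa`,
#'   `flagged` (spike failure).
#' @export
threshold_vs_conductance_curve <- function(config,
                                           g_values = c(0.04, 0.03, 0.02,
                                                        0.01, 0.005, 0.0025),
                                           step_pa = 400, step_ms = 3) {
  rows <- lapply(g_values, function(g) {
    cfg <- config; cfg$g_nav <- g
    hold <- find_holding_current(cfg)$pa
    cfg$holding_pa <- hold
    sim <- simulate_current_clamp(
      cfg, protocol_steps(c(0, step_pa, 0), c(200, step_ms, 40)),
      settle_ms = 500)
    i_pre <- round(700 / cfg$dt)
    h_pre <- sim$gates$h[i_pre]
    thr <- measure_model_threshold(sim, from_ms = 700)$threshold
    data.frame(g_nav = g, activatable = activatable_nav(cfg, h_pre),
               threshold = thr, holding_pa = hold, flagged = is.na(thr))
  })
  do.call(rbind, rows)
}

#' Simulate the model under ideal voltage clamp
#'
#' Integrates the gating variables along a commanded voltage waveform (no
#' series resistance) and reports the channel current densities; the peak
#' (most negative) Na current of each epoch is summarized.
#'
#' @param config a [model_config].
#' @param protocol data frame with columns `v_mv`, `dur_ms`.
#' @return list with `v_cmd`, `currents` (data frame, mA/cm2), `epoch`
#'   (epoch index per sample) and `peak_na` (data frame `epoch`, `v_mv`,
#'   `peak_i_na`).
#' @export
simulate_voltage_clamp <- function(config, protocol) {
  k <- config$kinetics
  dt <- config$dt
  v_cmd <- unlist(Map(function(v, d) rep(v, round(d / dt)),
                      protocol$v_mv, protocol$dur_ms))
  epoch <- unlist(Map(function(e, d) rep(e, round(d / dt)),
                      seq_len(nrow(protocol)), protocol$dur_ms))
  n <- length(v_cmd)
  v0 <- v_cmd[1]
  m <- k$minf(v0); h <- k$hinf(v0); nn <- k$ninf(v0)
  a <- k$ainf(v0); b <- k$binf(v0)
  ina <- ikdr <- iia <- numeric(n)
  for (t in seq_len(n)) {
    vv <- v_cmd[t]
    m <- m + (k$minf(vv) - m) * (1 - exp(-dt / k$tau_m(vv)))
    h <- h + (k$hinf(vv) - h) * (1 - exp(-dt / k$tau_h(vv)))
    nn <- nn + (k$ninf(vv) - nn) * (1 - exp(-dt / k$tau_n(vv)))
    a <- a + (k$ainf(vv) - a) * (1 - exp(-dt / k$tau_a(vv)))
    b <- b + (k$binf(vv) - b) * (1 - exp(-dt / k$tau_b(vv)))
    ina[t] <- config$g_nav * m^k$m_exp * h * (vv - config$e_na)
    ikdr[t] <- config$g_kdr * nn * (vv - config$e_k)
    iia[t] <- config$g_ia * a * b * (vv - config$e_k)
  }
  peak <- do.call(rbind, lapply(seq_len(nrow(protocol)), function(e) {
    sel <- epoch == e
    data.frame(epoch = e, v_mv = protocol$v_mv[e],
               peak_i_na = min(ina[sel]))
  }))
  list(v_cmd = v_cmd, epoch = epoch,
       currents = data.frame(i_na = ina, i_kdr = ikdr, i_ia = iia),
       peak_na = peak)
}

#' Slow-AHP buildup over 40 Hz spike trains
#'
#' Drives the model with trains of 3 ms current pulses at `rate_hz` and
#' summarizes the AHP following the last spike of each train: minimum
#' voltage, AHP area below the -60 mV holding level, voltage 100 ms after
#' the last pulse (the slow component), the voltage at slow-component onset
#' (where the repolarization rate first falls below 10% of its maximum),
#' and the A-type current trace during the AHP.
#'
#' @param config a [model_config]; its `holding_pa` should place rest at
#'   -60 mV.
#' @param n_spikes train lengths.
#' @param rate_hz train rate.
#' @param amp_pa,width_ms pulse shape.
#' @param post_ms analysis window after the last pulse, ms.
#' @return list with `summary` (data frame per train length) and `ahp`
#'   (list of post-train Vm segments) and `i_a` (list of A-type current
#'   segments).
#' @export
train_ahp_buildup <- function(config, n_spikes = c(1, 2, 4, 8, 16),
                              rate_hz = 40, amp_pa = 1000, width_ms = 3,
                              post_ms = 600) {
  dt <- config$dt
  out_rows <- list(); ahps <- list(); ias <- list()
  for (ns in n_spikes) {
    prot <- protocol_pulse_train(ns, rate_hz, amp_pa, width_ms,
                                 lead_ms = 200, post_ms = post_ms)
    sim <- simulate_current_clamp(config, prot, settle_ms = 500)
    v <- sim$trace$samples
    # every pulse must elicit exactly one spike
    period_n <- round(1000 / rate_hz / dt)
    t0 <- round(700 / dt)
    for (kp in seq_len(ns)) {
      w <- (t0 + (kp - 1) * period_n):(t0 + kp * period_n - 1)
      w <- w[w <= length(v)]
      if (sum(diff(v[w] > -23) == 1) < 1)
        stop(sprintf("pulse %d of the %d-spike train failed to elicit a spike",
                     kp, ns))
    }
    i_last <- t0 + (ns - 1) * period_n + round(width_ms / dt)
    seg <- v[i_last:min(i_last + round(post_ms / dt), length(v))]
    ia_seg <- sim$currents$i_ia[i_last:min(i_last + round(post_ms / dt),
                                           length(v))]
    tt <- (seq_along(seg) - 1) * dt
    i_tr <- which.min(seg[tt <= 100])
    # slow-component onset: repolarization rate falls below 10% of its max
    dvdt <- diff(seg) / dt
    rec <- dvdt[i_tr:length(dvdt)]
    on <- which(rec < 0.1 * max(rec, na.rm = TRUE))[1]
    v_slow_onset <- if (is.na(on)) NA_real_ else seg[i_tr + on - 1]
    out_rows[[length(out_rows) + 1]] <- data.frame(
      n_spikes = ns,
      ahp_min = min(seg), ahp_amplitude = min(seg) - (-60),
      area = sum(pmin(seg + 60, 0)) * dt,
      v_100ms = seg[round(100 / dt)],
      v_200ms = seg[round(200 / dt)],
      v_slow_onset = v_slow_onset)
    ahps[[as.character(ns)]] <- seg
    ias[[as.character(ns)]] <- ia_seg
  }
  list(summary = do.call(rbind, out_rows), ahp = ahps, i_a = ias)
}

#' Nernst equilibrium potential
#'
#' `E = (RT / zF) ln(c_out / c_in)`, in mV. With the recording solutions
#' (chloride: 135 mM outside from 125 NaCl + 4 KCl + 2x2 CaCl2 + 2 MgCl2,
#' 2 mM inside from 1 mM MgCl2, at 30 C) this gives ECl = -110 mV.
#'
#' @param c_in,c_out intra-/extracellular concentrations, mM (> 0).
#' @param z ionic valence (e.g. -1 for chloride).
#' @param temperature_k absolute temperature, K.
#' @return equilibrium potential, mV.
#' @export
nernst_potential <- function(c_in, c_out, z, temperature_k = 303.15) {
  if (any(c(c_in, c_out) <= 0)) stop("concentrations must be > 0")
  R <- 8.31446; FARADAY <- 96485.33
  1000 * R * temperature_k / (z * FARADAY) * log(c_out / c_in)
}
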
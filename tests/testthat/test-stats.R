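# within-cell fits -----------------------------------------------------

test_that("within_cell_fit recovers an exact line and flags degeneracy", {
  x <- 1:10
  f <- within_cell_fit(x, 2 * x + 1, "c1")
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$r, 1)
  expect_false(f$flagged)
  expect_true(within_cell_fit(rep(3, 10), rnorm(10))$flagged)
  expect_true(within_cell_fit(1:2, 1:2)$flagged)  # n < 3
})

# Holm correction ------------------------------------------------------

holm_brute <- function(p) {
  # direct step-down definition: sort, multiply by (m - i + 1), enforce
  # monotonicity sequentially, cap at 1
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, min(1, (m - i + 1) * p[o[i]]))
    adj[o[i]] <- running
  }
  adj
}

test_that("Holm correction matches hand and brute-force values", {
  expect_equal(holm_correction(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_correction(0.03), 0.03)
  expect_error(holm_correction(c(0.5, 1.2)), "0, 1")
  set.seed(11)
  for (i in 1:50) {
    m <- sample(1:8, 1)
    p <- round(runif(m), 3)
    expect_equal(holm_correction(p), holm_brute(p))
    expect_equal(holm_correction(p), p.adjust(p, "holm"))
    a <- holm_correction(p)
    expect_true(all(a >= p))
    expect_true(all(diff(a[order(p)]) >= 0))
  }
})

# population summaries -------------------------------------------------

test_that("population_summary matches hand arithmetic", {
  s <- population_summary(c(1, 2, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sem, 1 / sqrt(3), tolerance = 1e-9)   # sd = 1
  expect_equal(s$ci95, 1.96 / sqrt(3), tolerance = 1e-9)
  expect_equal(s$es, 2)                                # mean/SD
  expect_equal(s$t, 2 / (1 / sqrt(3)), tolerance = 1e-9)
  tt <- t.test(c(1, 2, 3))
  expect_equal(s$p, tt$p.value, tolerance = 1e-9)
  expect_true(population_summary(rep(0, 5))$flagged)
  expect_error(population_summary(1), "at least 2")
  # symmetric values around zero: es ~ 0, p near 1
  s2 <- population_summary(c(-2, -1, 1, 2))
  expect_equal(s2$es, 0)
  expect_equal(s2$p, 1)
})

# threshold model ------------------------------------------------------

make_threshold_table <- function(n_bursts = 30, noise = 0, seed = 1,
                                 beta = c(5, 0.8, -2, 0.01, 0.5)) {
  # linear law: thr = b0 + b1*amp + b2*slope + b3*dur + b4*vrest + eps
  set.seed(seed)
  rows <- list()
  t0 <- 0
  for (b in seq_len(n_bursts)) {
    sz <- sample(3:6, 1)
    amp <- runif(sz, -7, -3); slp <- runif(sz, 0.2, 1.5)
    dur <- runif(sz, 8, 25); vr <- rep(runif(1, -62, -58), sz)
    thr <- beta[1] + beta[2] * amp + beta[3] * slp + beta[4] * dur +
      beta[5] * vr + rnorm(sz, 0, noise)
    rows[[b]] <- data.frame(
      cell_id = "c1", burst = b, index_in_burst = seq_len(sz),
      threshold_time = t0 + seq_len(sz) * 20,
      threshold_value = thr,
      # feature columns describe the AHP *after* each AP; the model lags
      # them internally, so shift forward here
      ahp_amplitude = c(amp[-1], NA), ahp_slope = c(slp[-1], NA),
      ahp_duration = c(dur[-1], NA), v_rest = vr)
    t0 <- t0 + 1000 * b
  }
  do.call(rbind, rows)
}

test_that("threshold model recovers a noiseless linear law exactly", {
  d <- make_threshold_table(noise = 0)
  m <- suppressWarnings(fit_threshold_model(d))
  expect_equal(unname(m$coefficients),
               c(5, 0.8, -2, 0.01, 0.5), tolerance = 1e-6)
  expect_equal(m$r_squared, 1, tolerance = 1e-9)
  # interactions give no real improvement: BIC penalizes the larger model
  expect_gt(m$bic_interactions, m$bic)
})

test_that("threshold model: 95% CI coverage over replicate noisy datasets", {
  truth <- c(5, 0.8, -2, 0.01, 0.5)
  hits <- matrix(0L, 30, 5)
  for (rep in 1:30) {
    d <- make_threshold_table(n_bursts = 60, noise = 0.3, seed = 100 + rep)
    ci <- confint(fit_threshold_model(d)$fit)
    hits[rep, ] <- as.integer(truth >= ci[, 1] & truth <= ci[, 2])
  }
  # per-coefficient coverage of a 95% CI should rarely dip below 24/30
  expect_true(all(colSums(hits) >= 24))
  d <- make_threshold_table(n_bursts = 10, noise = 0.3, seed = 4)
  expect_error(fit_threshold_model(d[1:8, ]), "complete intraburst")
})

test_that("post-burst threshold prediction is consistent and continuous", {
  d <- make_threshold_table(noise = 0)
  m <- suppressWarnings(fit_threshold_model(d))
  tt <- seq(0, 900, by = 1)
  pred <- predict_threshold_after_burst(m, ahp_amplitude = -5,
                                        ahp_slope = 0.8, v_rest = -60,
                                        t_elapsed_ms = tt)
  expect_true(all(abs(diff(pred)) < 1))       # continuous linear map
  # at t equal to an observed duration the prediction equals the law
  expect_equal(pred[tt == 20],
               5 + 0.8 * (-5) - 2 * 0.8 + 0.01 * 20 + 0.5 * (-60),
               tolerance = 1e-6)
  expect_warning(predict_threshold_after_burst(m, -5, 0.8, -60, 1500),
                 "beyond 1 s")
  # zero duration coefficient -> flat curve
  d0 <- make_threshold_table(noise = 0, beta = c(5, 0.8, -2, 0, 0.5))
  m0 <- suppressWarnings(fit_threshold_model(d0))
  p0 <- predict_threshold_after_burst(m0, -5, 0.8, -60, tt)
  expect_lt(diff(range(p0)), 1e-6)
})

test_that("overshoot detection flags a constructed crossing", {
  d <- make_threshold_table(noise = 0)
  m <- suppressWarnings(fit_threshold_model(d))
  fs <- 25000
  base <- predict_threshold_after_burst(m, -5, 0.8, -60, 0)
  v <- rep(base - 10, 10000)
  tr <- vm_trace(v, fs = fs)
  out <- detect_overshoot(tr, 1000L, 9000L, m, -5, 0.8, -60)
  expect_false(out$overshoot)
  v2 <- v; v2[5000:5100] <- base + 3   # crosses the rising predicted curve
  out2 <- detect_overshoot(vm_trace(v2, fs = fs), 1000L, 9000L, m,
                           -5, 0.8, -60)
  expect_true(out2$overshoot)
  expect_equal(out2$crossing_time, 5000 / 25, tolerance = 0.2)
})

# burst models ---------------------------------------------------------

make_burst_table <- function(n = 400, seed = 2, tau_coef = 0,
                             noise = 0) {
  set.seed(seed)
  vr <- runif(n, -62, -58); amp <- runif(n, -8, -3)
  slp <- runif(n, 0.2, 1.5)
  tau <- rep(runif(20, 120, 250), length.out = n)
  y_freq <- 3 + 0.05 * vr - 0.1 * amp + 0.6 * slp +
    0.002 * vr * amp + tau_coef * tau / 100 + rnorm(n, 0, noise)
  y_size <- 0.3 + 0.004 * vr - 0.03 * amp + 0.05 * slp +
    tau_coef * tau / 200 + rnorm(n, 0, noise)
  data.frame(cell_id = rep(sprintf("c%02d", 1:20), length.out = n),
             size = pmax(4, round(exp(exp(y_size)))),
             intraburst_freq = exp(y_freq),
             v_rest = vr, first_ahp_amplitude = amp,
             first_ahp_slope = slp, slow_tau = tau,
             y_size_true = y_size, y_freq_true = y_freq)
}

test_that("burst models: noiseless law gives R^2 = 1; ANOVA detects tau iff present", {
  d <- make_burst_table(tau_coef = 0)
  # make the endogenous variables exactly the generating law
  d$intraburst_freq <- exp(d$y_freq_true)
  d$size2 <- d$size  # size is rounded; use frequency for the exact check
  m <- suppressWarnings(fit_burst_models(d, include_slow_tau = TRUE))
  expect_gt(m$freq_model$r_squared, 0.999)
  expect_gt(m$comparison$p[m$comparison$endo == "freq"], 0.01) # tau absent
  d2 <- make_burst_table(tau_coef = 0.5, noise = 0.05)
  m2 <- fit_burst_models(d2, include_slow_tau = TRUE)
  expect_lt(m2$comparison$p[m2$comparison$endo == "freq"], 1e-6) # tau present
  expect_gt(m2$comparison$f2[m2$comparison$endo == "freq"], 0)
})

test_that("burst-size transform is defined for all retained bursts", {
  d <- make_burst_table(noise = 0.1)
  d$size[1] <- 3   # filtered out by the > 3 rule
  m <- fit_burst_models(d)
  expect_equal(m$n_bursts, sum(d$size > 3))
  expect_true(all(is.finite(log(log(d$size[d$size > 3])))))
  expect_equal(log(log(4)), 0.3266343, tolerance = 1e-6)
})

test_that("permuting tau across cells kills the model comparison", {
  d <- make_burst_table(tau_coef = 0.5, noise = 0.2, seed = 8)
  set.seed(9)
  d$slow_tau <- sample(d$slow_tau)
  m <- fit_burst_models(d, include_slow_tau = TRUE)
  expect_gt(m$comparison$p[m$comparison$endo == "freq"], 0.001)
})

# OLS closed-form oracle ------------------------------------------------

test_that("OLS fits match the normal equations on a 2-predictor design", {
  set.seed(5)
  X <- cbind(1, rnorm(40), runif(40))
  y <- X %*% c(2, -1, 0.5) + rnorm(40, 0, 0.1)
  beta_ne <- solve(t(X) %*% X, t(X) %*% y)   # normal equations directly
  d <- data.frame(y = y, x1 = X[, 2], x2 = X[, 3])
  f <- lm(y ~ x1 + x2, data = d)
  expect_equal(unname(coef(f)), as.numeric(beta_ne), tolerance = 1e-10)
})

# JZS Bayes factor ------------------------------------------------------

jzs_oracle <- function(t, n, r = 0.707) {
  # independent route: integrate the noncentral-t likelihood against the
  # Cauchy prior on the standardized effect size
  # dt(..., ncp) warns about 'pnt' precision far in the tails; harmless here
  num <- suppressWarnings(
    integrate(function(d) dt(t, n - 1, ncp = sqrt(n) * d) *
                dcauchy(d, 0, r),
              -Inf, Inf, rel.tol = 1e-12)$value)
  num / dt(t, n - 1)
}

test_that("JZS Bayes factor: null-favouring at t = 0, monotone in |t|", {
  expect_lt(jzs_bayes_factor(0, 20), 1)
  bfs <- sapply(c(0, 0.5, 1, 2, 3, 5), jzs_bayes_factor, n = 15)
  expect_true(all(diff(bfs) > 0))
  expect_error(jzs_bayes_factor(Inf, 10), "finite")
  expect_error(jzs_bayes_factor(1, 1), "n must")
})

test_that("JZS Bayes factor agrees with the quadrature oracle to 1e-6", {
  for (case in list(c(2.5, 19), c(0, 20), c(-1.3, 8), c(4, 50))) {
    bf <- jzs_bayes_factor(case[1], case[2])
    expect_equal(bf, jzs_oracle(case[1], case[2]),
                 tolerance = 1e-6)
  }
})

test_that("overshoot fraction is low with a strong slow AHP, high without", {
  overshoot_frac <- function(slow_amp) {
    rec <- generate_cell_recording(
      generator_params(seed = 21, n_bursts = 15, slow_amp_max = slow_amp))
    f <- extract_cell_features(rec$trace)
    m <- fit_threshold_model(f$ap_table)
    a <- f$ap_table; seg <- f$segmentation
    v <- rec$trace$samples
    hits <- 0; tot <- 0
    for (k in seq_along(seg$bursts)) {
      ix <- seg$bursts[[k]]; last <- ix[length(ix)]
      i0 <- a$peak_index[last] + which.min(v[a$peak_index[last] + 1:7500])
      nxt <- if (last < nrow(a)) a$threshold_index[last + 1] else length(v)
      i1 <- min(i0 + 12500, nxt, length(v))   # up to 500 ms after the trough
      if (i1 - i0 < 2500) next
      amp <- a$ahp_amplitude[last]; slp <- a$ahp_slope[last]
      if (!is.finite(amp) || !is.finite(slp)) next
      o <- detect_overshoot(rec$trace, i0, i1, m, amp, slp, a$v_rest[last])
      tot <- tot + 1; hits <- hits + o$overshoot
    }
    hits / tot
  }
  expect_lt(overshoot_frac(-3), 0.2)      # slow AHP keeps Vm below threshold
  expect_gt(overshoot_frac(-0.01), 0.5)   # removing it exposes overshoots
})
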
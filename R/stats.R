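#' Within-cell linear fit
#'
#' Ordinary least-squares regression of `y` on `x` for one cell, with the
#' Pearson correlation and its two-sided p-value. These per-cell fits are
#' the first stage of the two-stage analysis (fit within each cell, then
#' test the population of slopes/correlations against zero).
#'
#' @param x,y paired finite observations (n >= 3).
#' @param cell_id label.
#' @return list of class `within_cell_fit`: `cell_id`, `slope`, `intercept`,
#'   `r`, `p_raw`, `n_points`, `flagged` (degenerate x).
#' @export
within_cell_fit <- function(x, y, cell_id = "cell") {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  out <- list(cell_id = cell_id, slope = NA_real_, intercept = NA_real_,
              r = NA_real_, p_raw = NA_real_, n_points = length(x),
              flagged = TRUE)
  class(out) <- "within_cell_fit"
  if (length(x) < 3) return(out)
  if (stats::var(x) == 0) return(out)
  f <- stats::lm(y ~ x)
  r <- stats::cor(x, y)
  n <- length(x)
  tval <- r * sqrt((n - 2) / max(1e-300, 1 - r^2))
  out$slope <- unname(stats::coef(f)[2])
  out$intercept <- unname(stats::coef(f)[1])
  out$r <- r
  out$p_raw <- 2 * stats::pt(-abs(tval), n - 2)
  out$flagged <- FALSE
  out
}

#' Holm (step-down Bonferroni) correction
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values (monotone, capped at 1), in the input order.
#' @export
holm_correction <- function(p) {
  stop_if_not_prob(p)
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  adj <- pmin(1, (m - seq_len(m) + 1) * p[o])
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Population summary of per-cell values
#'
#' One-sample t-test of the per-cell values against zero, with the 95% CI
#' defined as 1.96 x SEM and the effect size as mean/SD (Cohen's d).
#'
#' @param values per-cell values (n >= 2).
#' @return list of class `population_summary`: `mean`, `sem`, `ci95`, `es`,
#'   `t`, `p`, `n_cells`, `flagged` (zero variance).
#' @export
population_summary <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) stop("need at least 2 finite values")
  s <- stats::sd(values)
  m <- mean(values)
  sem <- s / sqrt(n)
  flagged <- s == 0
  tval <- if (flagged) NaN else m / sem
  out <- list(mean = m, sem = sem, ci95 = 1.96 * sem,
              es = if (flagged) NaN else m / s,
              t = tval,
              p = if (flagged) NaN else 2 * stats::pt(-abs(tval), n - 1),
              n_cells = n, flagged = flagged)
  class(out) <- "population_summary"
  out
}

#' Per-cell linear threshold model
#'
#' Fits the intraburst AP threshold (first AP of each burst excluded) as a
#' linear combination of AHP amplitude, AHP slope, AHP duration and the
#' burst resting potential, by OLS. The interaction-augmented variant (all
#' pairwise interactions) is also fitted and both BICs reported; in the
#' recordings the interactions never paid their BIC cost.
#'
#' @param ap_table per-AP table (from [extract_cell_features]) with columns
#'   `ahp_amplitude`, `ahp_slope`, `ahp_duration`, `v_rest`,
#'   `threshold_value`, `index_in_burst`. The AHP regressors of AP i are
#'   those of the AHP *preceding* it (lag of the feature columns, which
#'   describe the AHP following each AP).
#' @param cell_id which cell to fit.
#' @param min_points minimum complete intraburst APs.
#' @return list of class `threshold_model`: `fit` (lm), `coefficients`,
#'   `r_squared`, `n`, `bic`, `bic_interactions`.
#' @export
fit_threshold_model <- function(ap_table, cell_id = NULL, min_points = 10) {
  d <- ap_table
  if (!is.null(cell_id)) d <- d[d$cell_id == cell_id, , drop = FALSE]
  # regressors for AP i are the features of the AHP that precedes it
  d <- d[order(d$threshold_time), , drop = FALSE]
  lag1 <- function(x) c(NA, x[-length(x)])
  dd <- data.frame(threshold = d$threshold_value,
                   ahp_amplitude = lag1(d$ahp_amplitude),
                   ahp_slope = lag1(d$ahp_slope),
                   ahp_duration = lag1(d$ahp_duration),
                   v_rest = d$v_rest,
                   index_in_burst = d$index_in_burst,
                   burst = d$burst,
                   prev_burst = lag1(d$burst))
  dd <- dd[!is.na(dd$index_in_burst) & dd$index_in_burst > 1 &
             !is.na(dd$prev_burst) & dd$prev_burst == dd$burst, ]
  dd <- dd[stats::complete.cases(dd[, 1:5]), ]
  if (nrow(dd) < min_points)
    stop(sprintf("need >= %d complete intraburst APs, have %d",
                 min_points, nrow(dd)))
  f <- stats::lm(threshold ~ ahp_amplitude + ahp_slope + ahp_duration +
                   v_rest, data = dd)
  qr_rank <- f$rank
  if (qr_rank < 5) {
    bad <- names(stats::coef(f))[is.na(stats::coef(f))]
    stop("rank-deficient design; offending columns: ",
         paste(bad, collapse = ", "))
  }
  fi <- stats::lm(threshold ~ (ahp_amplitude + ahp_slope + ahp_duration +
                                 v_rest)^2, data = dd)
  out <- list(cell_id = cell_id %||% unique(d$cell_id)[1],
              fit = f, coefficients = stats::coef(f),
              r_squared = summary(f)$r.squared, n = nrow(dd),
              bic = stats::BIC(f), bic_interactions = stats::BIC(fi),
              data = dd)
  class(out) <- "threshold_model"
  out
}

#' Predicted post-burst threshold as a function of elapsed time
#'
#' Uses a fitted [fit_threshold_model] to predict the AP threshold that
#' would be expected after the last AP of a burst, as a function of the time
#' elapsed since the last AHP peak (which plays the role of the AHP-duration
#' regressor, the other regressors being fixed at the burst's last-AHP
#' values).
#'
#' @param model a `threshold_model`.
#' @param ahp_amplitude,ahp_slope,v_rest last-AHP features of the burst.
#' @param t_elapsed_ms times since the last AHP peak, ms.
#' @return numeric vector of predicted thresholds (mV); a warning is issued
#'   when extrapolating beyond 1 s.
#' @export
predict_threshold_after_burst <- function(model, ahp_amplitude, ahp_slope,
                                          v_rest, t_elapsed_ms) {
  if (any(t_elapsed_ms > 1000))
    warning("extrapolating the threshold model beyond 1 s")
  nd <- data.frame(ahp_amplitude = ahp_amplitude, ahp_slope = ahp_slope,
                   ahp_duration = t_elapsed_ms, v_rest = v_rest)
  unname(stats::predict(model$fit, newdata = nd))
}

#' Detect post-burst threshold overshoot
#'
#' Flags whether the membrane potential after the last AP of a burst rises
#' above the predicted threshold curve without producing a further AP.
#'
#' @param trace a [vm_trace].
#' @param ahp_peak_index sample index of the last AHP peak.
#' @param end_index last sample to inspect (e.g. the next spike's threshold
#'   index, or the end of the available segment).
#' @param model a `threshold_model`.
#' @param ahp_amplitude,ahp_slope,v_rest last-AHP features for the
#'   prediction.
#' @return list with `overshoot` (logical), `crossing_time` (ms, `NA` when
#'   none) and `margin` (max of Vm minus predicted threshold, mV).
#' @export
detect_overshoot <- function(trace, ahp_peak_index, end_index, model,
                             ahp_amplitude, ahp_slope, v_rest) {
  idx <- ahp_peak_index:end_index
  t_el <- (idx - ahp_peak_index) * 1000 / trace$fs
  pred <- suppressWarnings(
    predict_threshold_after_burst(model, ahp_amplitude, ahp_slope, v_rest,
                                  t_el))
  diffv <- trace$samples[idx] - pred
  hit <- which(diffv > 0)
  list(overshoot = length(hit) > 0,
       crossing_time = if (length(hit)) index_to_time(trace, idx[hit[1]])
       else NA_real_,
       margin = max(diffv))
}

#' Pooled burst-size and burst-frequency models
#'
#' Pools bursts across cells (only bursts with more than three APs) and fits
#' OLS models of `log(log(size))` and `log(frequency)` on the burst resting
#' potential and the first-AHP amplitude and slope with all their
#' interactions. When `include_slow_tau` is `TRUE`, extended models adding
#' the per-cell slow-AHP time constant (main effect plus its two-way
#' interactions with the three predictors) are fitted and compared with the
#' base models by sequential (type-I) ANOVA, with Cohen's f-squared between
#' models.
#'
#' @param burst_table pooled per-burst table with columns `size`,
#'   `intraburst_freq`, `v_rest`, `first_ahp_amplitude`, `first_ahp_slope`
#'   and, if `include_slow_tau`, `slow_tau`.
#' @param include_slow_tau add the slow-AHP time constant?
#' @param min_size smallest burst size retained is `min_size + 1`.
#' @return list with `size_model`, `freq_model` (each: `fit`, `r_squared`,
#'   `f`, `df`, `bic`, `n`), and when requested `size_ext`, `freq_ext`,
#'   `comparison` (data frame with type-I ANOVA F, df, p and f2 per
#'   endogenous variable), and `n_excluded` (incomplete rows dropped).
#' @export
fit_burst_models <- function(burst_table, include_slow_tau = FALSE,
                             min_size = 3) {
  d <- burst_table[burst_table$size > min_size, , drop = FALSE]
  need <- c("size", "intraburst_freq", "v_rest", "first_ahp_amplitude",
            "first_ahp_slope", if (include_slow_tau) "slow_tau")
  cc <- stats::complete.cases(d[, need])
  n_excluded <- sum(!cc)
  d <- d[cc, , drop = FALSE]
  d$y_size <- log(log(d$size))      # defined: size >= 4 > e
  d$y_freq <- log(d$intraburst_freq)
  base_rhs <- "v_rest * first_ahp_amplitude * first_ahp_slope"
  mk <- function(endo, rhs) {
    f <- stats::lm(stats::as.formula(paste(endo, "~", rhs)), data = d)
    sm <- summary(f)
    list(fit = f, r_squared = sm$r.squared,
         f = unname(sm$fstatistic[1]),
         df = unname(sm$fstatistic[2:3]),
         bic = stats::BIC(f), n = nrow(d))
  }
  out <- list(size_model = mk("y_size", base_rhs),
              freq_model = mk("y_freq", base_rhs),
              n_excluded = n_excluded, n_bursts = nrow(d))
  if (include_slow_tau) {
    ext_rhs <- paste(base_rhs,
                     "+ slow_tau + slow_tau:(v_rest + first_ahp_amplitude +",
                     "first_ahp_slope)")
    out$size_ext <- mk("y_size", ext_rhs)
    out$freq_ext <- mk("y_freq", ext_rhs)
    cmp <- function(base, ext) {
      a <- stats::anova(base$fit, ext$fit)  # sequential (type-I) comparison
      data.frame(F = a$F[2], df1 = a$Df[2], df2 = a$Res.Df[2],
                 p = a$`Pr(>F)`[2],
                 f2 = (ext$r_squared - base$r_squared) /
                   (1 - ext$r_squared))
    }
    out$comparison <- rbind(
      cbind(endo = "size", cmp(out$size_model, out$size_ext)),
      cbind(endo = "freq", cmp(out$freq_model, out$freq_ext)))
  }
  out
}

#' JZS Bayes factor for a one-sample t-test
#'
#' Jeffreys-Zellner-Siow Bayes factor (alternative over null) for a
#' one-sample t statistic, with a Cauchy prior of scale `r_scale` (default
#' 0.707) on the standardized effect size. Computed by numerical integration
#' of the marginal likelihood over the g-prior representation of the Cauchy
#' (g ~ inverse-gamma(1/2, r^2/2)).
#'
#' @param t observed t statistic.
#' @param n sample size (>= 2).
#' @param r_scale Cauchy prior scale.
#' @return BF10 (numeric scalar); values below 1 favour the null.
#' @export
jzs_bayes_factor <- function(t, n, r_scale = 0.707) {
  if (!is.finite(t)) stop("t must be finite")
  if (n < 2) stop("n must be >= 2")
  nu <- n - 1
  null_lik <- (1 + t^2 / nu)^(-(nu + 1) / 2)
  integrand <- function(g) {
    (1 + n * g)^(-1 / 2) *
      (1 + t^2 / ((1 + n * g) * nu))^(-(nu + 1) / 2) *
      (r_scale^2 / 2)^(1 / 2) / gamma(1 / 2) *
      g^(-3 / 2) * exp(-r_scale^2 / (2 * g))
  }
  alt_lik <- stats::integrate(integrand, 0, Inf, rel.tol = 1e-10,
                              abs.tol = 0)$value
  alt_lik / null_lik
}
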
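---
title: "Methods: burst and AHP analysis for mitral-cell recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: burst and AHP analysis for mitral-cell recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ahpburst` implements an analysis of spontaneous mitral-cell bursting built
on one mechanistic idea: the action-potential threshold tracks the recent
trajectory of the membrane potential through the inactivation state of
voltage-gated Na⁺ channels. Hyperpolarization — a subthreshold oscillation
trough, an inhibitory input, or the afterhyperpolarization (AHP) of a
preceding spike — recovers Na_v channels from inactivation and lowers the
threshold; the fast AHP thereby sustains the burst, and a slowly
accumulating AHP component terminates it. This vignette documents the
algorithms, the tunable parameters, the synthetic-data generator, the
numerical choices, and what the tests do and do not establish.

## Detection

**Spikes.** An AP is an upward crossing of the detection potential
(`v_detect = -23` mV) with crossings closer than `min_isi = 1` ms to the
last accepted event discarded. These are operating conventions for
somatic whole-cell recordings at 25 kHz; per-cell oddities (one recorded
cell needed −43 mV because of small first spikes, another a 0.8×MAD
multiplier in the burst recursion) are handled by passing different
arguments, never by special-casing cells in code.

**Thresholds.** Two criteria coexist because they suit different data. On
experimental traces the threshold is the first point of strictly positive
acceleration (second derivative of V_m) on the AP rising phase, searching
backward from the point of maximum acceleration; raw double
differentiation at 25 kHz is noise-dominated, so derivatives come from a
Savitzky–Golay quadratic fit over a ±0.15 ms window (`smooth_ms = 0.3`,
exposed). The rising phase is the interval from the last local minimum of
the smoothed trace before the peak to the peak. Two near-identical
bound definitions exist for the backward search (maximum acceleration vs
maximum depolarization rate); both are implemented (`bound =`), the
maximum-acceleration bound is the default. On model traces the threshold
is the voltage where dV/dt first exceeds 40 mV/ms; see *Numerics* for the
interpolation this requires.

**Bursts.** Consecutive spikes whose inter-spike interval (ISI) is
strictly below a threshold tISI share a burst. The tISI starts at 90 ms
and is recomputed as `median(intraburst ISIs) + 4 × MAD` — with the *raw*
MAD (constant 1), which is what makes the worked example
`{10, 12, 8, 12} → median 11, MAD 1 → tISI 15` come out — iterating while
the new value is smaller. The recursion is guarded in two ways: a floor at
`min_isi`, and a revert-to-previous rule for the degenerate case MAD = 0
with all ISIs equal, where the strict-< grouping at the new tISI would
orphan every burst; the last burst-bearing segmentation is then returned
with a warning. Groups smaller than two spikes become isolated APs.

## Features

Per burst, the resting potential `V_rest` is the median V_m of the
preceding spike-free interval, trimmed by half the final tISI at its start
and 5 ms at its end, and the fluctuation amplitude is the maximum of the
same window; intervals shorter than 200 ms inherit both values from the
previous burst, and a first burst without a usable interval is excluded.
The pre-AP potential is found by stepping backward from the threshold in
1 ms steps until the current sample exceeds the running minimum (up to the
threshold) by at least 0.4 mV; the rebound criterion is read against the
running minimum — the text permits either reading; this one is monotone and
robust. The AHP amplitude is trough minus `V_rest` (negative), its slope a
regression over the time span where V_m lies within 20–60 % of the range
from the AHP trough (0 %) to the *previous* AP threshold (100 %) — the
anchor on the previous AP lets the same rule apply after the last spike of
a burst — and its duration runs from the trough to the next threshold.
Voltage bands are converted to time spans by the first/last band-edge
crossings. When the ISI is long the trough search is capped at 300 ms.
Normalized thresholds map `V_rest` to 0 and the fluctuation maximum to 1.

The slow-AHP time constant uses only bursts followed by at least 500 ms of
silence: their post-burst segments are aligned on the AHP trough
(nearest-sample, no interpolation), a median trace is formed, and
`v0 + A·exp(-t/tau)` is fitted over 50–500 ms. The fit profiles `tau` on a
log grid with the linear pair solved in closed form, then refines by
golden-section search, bounded to `[1, 5000]` ms — deterministic, no
starting-value failures. Segments are sampled on a 1 ms grid before the
median; the slow component carries no information above ~10 Hz and this
keeps the cost at 25 kHz negligible. Cells without qualifying bursts
report the fit as unavailable rather than guessing (in the original
cohort this affected 7 of 49 cells).

## Statistics

Inference is two-stage, not hierarchical: OLS fits within each cell, then
one-sample t tests of the per-cell slopes and correlation coefficients
against zero, with 95 % CI defined as 1.96·SEM and effect size as mean/SD
(Cohen's d; the original analysis never defines "ES", so this is a
documented package choice, with standardized slopes playing that role for
regressions). Holm's step-down correction is applied within an analysis
family. The per-cell threshold model regresses intraburst thresholds
(first AP of each burst excluded) on the *preceding* AHP's amplitude,
slope and duration plus `V_rest`; the interaction-augmented variant is
fitted alongside and both BICs reported — interactions never pay their
way, matching the original observation. The fitted model predicts the
threshold after the last AP as a function of time elapsed since the last
AHP trough (the duration regressor), and `detect_overshoot()` flags bursts
whose membrane potential exceeds that curve without firing. Pooled burst
models use `log(log(size))` and `log(frequency)` (variance-stabilizing
transforms; sizes ≤ 3 are excluded so the double log is defined) on
`V_rest` × first-AHP amplitude × first-AHP slope with all interactions;
"type-I ANOVA" is read as the sequential sum-of-squares comparison of the
nested models with and without the per-cell slow-AHP time constant (main
effect plus its two-way interactions), with Cohen's
f² = (R²_full − R²_base)/(1 − R²_full) between them. Missing features drop
the row, with the count reported. The JZS Bayes factor integrates the
g-prior representation of the Cauchy(0.707) effect-size prior; the test
suite checks it against an independent quadrature route (noncentral-t
likelihood against the Cauchy density) to 10⁻⁶ relative error.

## The conductance-based model

A single compartment with Na_v (m³h), delayed-rectifier K⁺ (n), A-type K⁺
(a·b) and passive conductances at the published densities (0.02, 0.0002,
0.003, 3.33·10⁻⁵ S/cm²) and reversals (+90, −91, −28.878 mV), C_m =
1 µF/cm², nominal 30 °C with no additional q10 scaling. The exact rate
equations of the source models are not printed anywhere and the deposited
code is unreachable offline, so the package ships its own Hodgkin–Huxley
parameterization in `inst/extdata/kinetics.json` — the single place where
the constants are pinned. The shapes follow standard practice (Boltzmann
steady states; Gaussian-bell or constant time constants) and were
validated against the stated behaviours of the original model rather than
transcribed: the base model must rest at exactly −60 mV with zero holding
current (the A-type activation midpoint, −39.57 mV, is the one constant
pinned by that condition — the same role the −28.878 mV leak reversal
played for the original authors); single 3 ms/400 pA pulses must elicit
single spikes at every Na_v density from 0.04 down to 0.0025 S/cm² (which
requires Na⁺ inactivation to be slow, ~8 ms, in the subthreshold
depolarized band and fast elsewhere); recovery from inactivation must be
complete within 10 ms at −70 mV (the duration-insensitivity of the
voltage-clamp protocol); and the A-type inactivation gate must
*deinactivate* across 40 Hz trains (its recovery accelerates ~5× below
−62 mV — physiologically standard asymmetry; the printed 150 ms original /
50 ms modified values are its depolarized inactivation time constants, and
the printed half-inactivation and slope pairs, −110 mV & 0.056 mV⁻¹ vs
−90 mV & 0.1 mV⁻¹, enter unchanged). The membrane area only scales
absolute currents; the default is a 30 µm spherical soma, which puts the
no-A-type holding current (−25.9 pA) in the published range, and all
headline checks use area-independent quantities.

## Numerics

Integration is fixed-step (0.1 ms default, configurable) with Strang
splitting: a half-step exponential-Euler gate update at the old voltage, a
full-step exponential voltage update (exact when conductances are frozen
over the step — hence exact in the passive limit, where the RC closed form
is matched to < 0.1 %), and a second half-step gate update at the new
voltage. The design-stage alternative, an implicit-Euler voltage update,
is equally stable but only first-order; at 0.1 ms its transient error
already exceeds the passive-limit tolerance, which is why the exponential
update was chosen. The scheme is second order: halving dt moves the
measured spike threshold by < 0.2 mV. The dV/dt > 40 mV/ms threshold
measurement interpolates the crossing on the *midpoint* derivative grid —
at 40 mV/ms and 0.1 ms steps the voltage advances 4 mV per sample, so
reporting the first supra-cut sample (or interpolating at the wrong grid)
quantizes the threshold by millivolts. Protocols that compare thresholds
across conditions 2.5 mV apart (the pre-hyperpolarization curves) are run
at dt = 0.025 ms, where the residual discretization ripple (~0.05 mV at
0.1 ms) is negligible. Holding currents are found by bisection on the
simulated steady state, cross-checked in the tests against the algebraic
zero-net-current condition with all gates at steady state.

## The synthetic-data generator

The generator builds what the analysis expects to see, with known ground
truth: a −60 mV baseline carrying a zero-median sinusoidal oscillation
(1.5 mV peak) plus AR(1) noise (0.1 mV, ~2 ms correlation); bursts of 2–12
APs at ~50 Hz preceded by a smooth hyperpolarizing dip of random depth
(0.6–3 mV); stereotyped AP templates (0.3 ms half-cosine rise to +30 mV,
1 ms fall to the AHP trough) stitched at the threshold sample; intraburst
AHP troughs at −5 mV relative to rest (±0.3 mV jitter) recovering
exponentially with τ_fast = 8 ms so the trace reaches the next threshold
exactly at the next spike time; and a post-burst tail
`A_f·e^(-t/8) + A_s·e^(-t/171.66)` whose slow amplitude saturates with
burst size (`A_s = -3·(1 - e^(-0.3·n))` mV). Each threshold follows
`threshold_base − s·(preAP − V_rest) + ε` with `s = −0.37` mV per mV of
hyperpolarization depth and ε of 0.3 mV — the scatter that gives the
realistic within-cell R ≈ 0.5–0.8 instead of a degenerate perfect fit.
Two generator choices deserve emphasis:

- *The realized pre-AP potential is located with the analyzer's own
  backward-rebound rule* before the threshold is set from it. Defining the
  truth by a different window than the measurement would act as
  errors-in-variables noise and attenuate the recovered slope by several
  percent — enough to bias the population CI off the generating value.
- *The oscillation frequency defaults to 40 Hz*, the canonical
  olfactory-bulb gamma band; the recordings describe interburst
  oscillations only as "fast", with no spectrum, so the default is a
  placeholder in that sense. A slow placeholder (a few Hz) is also
  scientifically wrong and makes the slow-AHP fit unidentifiable, since
  the oscillation period then rivals the 50–500 ms fit window. Oscillations
  fade back in over ~500 ms after a burst, reflecting the visually clean
  early post-burst traces; with both choices the cohort-level slow-AHP tau
  recovers within ~5 % and per-cell estimates within ~10 %.

What the generator does **not** emulate: synaptic input, channel noise,
the full covariance structure of real cells (e.g. the correlation between
V_rest and AHP shape), spike-height variability, electrode artifacts, or
bimodal resting potentials. A green round-trip test therefore establishes
that the pipeline measures what the definitions say on clean, well-posed
data — not that it is robust to every pathology of real recordings.

## Known limitations

ABF and HDF5 I/O are out of this build (no offline readers); traces enter
as CSV. The channel kinetics are a validated stand-in, not a transcription
of the deposited model code, so absolute thresholds and holding currents
match the published ones in sign and order of magnitude but not digit for
digit; all claims tested against the model are therefore qualitative
(monotonicity, amplification, growth) or self-consistent (convergence,
closed forms). Membrane resistance is not estimated from traces; the QC
filter takes it as metadata. The post-AHP rebound depolarization is
observed in data but not algorithmically defined, and is not extracted.
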
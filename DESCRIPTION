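Package: ahpburst
Title: Burst and Afterhyperpolarization Analysis for Mitral Cell Recordings
Version: 0.1.0
Authors@R: person("Analysis", "Pipeline", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing spontaneous bursting in olfactory-bulb mitral
    cells from current-clamp membrane-potential traces. Detects action
    potentials and their voltage thresholds (second-derivative onset or dV/dt
    criterion), segments spike trains into bursts with a recursive
    median + MAD inter-spike-interval threshold, extracts per-burst resting
    potential, pre-spike potential and slope, afterhyperpolarization (AHP)
    amplitude, slope and duration, and the slow-AHP time constant. Provides
    the statistical layer used to relate AHP shape to burst properties
    (within-cell regressions with Holm correction, population summaries,
    per-cell threshold models with post-burst prediction, pooled burst-size
    and burst-frequency models, JZS Bayes factors), a synthetic-recording
    generator with known ground truth, and a single-compartment
    conductance-based neuron model (Nav, delayed-rectifier K, A-type K,
    passive) reproducing threshold shifts by sodium-channel deinactivation
    and slow-AHP buildup over spike trains.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
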
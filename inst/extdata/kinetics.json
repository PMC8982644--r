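{
  "comment": "Hodgkin-Huxley gating parameterization of the single-compartment mitral-cell model. Steady states are Boltzmann curves xinf(v) = 1/(1+exp(-(v-vh)/k)); time constants are base + amp*exp(-((v-tau_vmid)/tau_width)^2) ms unless noted. The A-type activation midpoint a.vh is pinned by requiring zero net membrane current at -60 mV with the printed conductance densities and reversal potentials (the validation condition for the resting state). The A-type inactivation gate b uses the variant-specific midpoint/slope and a voltage-dependent time constant: tau_b(v) = tau_inact*(rec_frac + (1-rec_frac)/(1+exp(-(v-tau_vmid)/tau_k))), i.e. the printed tau_inact at depolarized potentials and ~5x faster recovery when hyperpolarized.",
  "cm_uf_cm2": 1.0,
  "nav": {
    "m": {"vh": -40.0, "k": 6.0, "exponent": 3,
          "tau_base": 0.05, "tau_amp": 0.25, "tau_vmid": -40.0, "tau_width": 25.0},
    "h": {"vh": -62.0, "k": -5.5, "exponent": 1,
          "tau_base": 0.4, "tau_amp": 8.0, "tau_vmid": -35.0, "tau_width": 12.0}
  },
  "kdr": {
    "n": {"vh": -35.0, "k": 7.0, "exponent": 1,
          "tau_base": 0.8, "tau_amp": 5.0, "tau_vmid": -32.0, "tau_width": 26.0}
  },
  "ia": {
    "a": {"vh": -39.5725303576, "k": 13.0, "exponent": 1, "tau_const": 2.0},
    "b_original": {"vh": -110.0, "slope_per_mv": 0.056, "tau_inact": 150.0},
    "b_modified": {"vh": -90.0, "slope_per_mv": 0.1, "tau_inact": 50.0},
    "b_tau": {"rec_frac": 0.2, "tau_vmid": -62.0, "tau_k": 3.0}
  }
}
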
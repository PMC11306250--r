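{
  "WT": {
    "k1_0": 4.7, "k2_0": 46.0, "d1": 1.8, "d2": 2.8, "k_att": 0.5,
    "ws_total": 18.0, "kappa_pre": 0.25, "kappa_rigor": 0.25,
    "sf": {"k_adp": 3.7, "k2": 20.8}
  },
  "S267A": {
    "k1_0": 4.7, "k2_0": 46.0, "d1": 1.8, "d2": 2.8, "k_att": 0.5,
    "ws_total": 17.4, "kappa_pre": 0.25, "kappa_rigor": 0.25,
    "sf": {"k_adp": 3.0, "k2": 24.2}
  },
  "S267E": {
    "k1_0": 19.4, "k2_0": 55.0, "d1": 1.8, "d2": 2.8, "k_att": 0.5,
    "ws_total": 18.2, "kappa_pre": 0.25, "kappa_rigor": 0.35,
    "sf": {"k_adp": 16.3, "k2": 46.4}
  }
}
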
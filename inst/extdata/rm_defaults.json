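{
  "comment": "Default Rosenzweig-MacArthur metacommunity parameters. Chosen by a numeric scan so that the single-patch coexistence state crosses a Hopf bifurcation as K increases (crossing near K = 1.47); equal dispersal rates keep the homogeneous mode the first to destabilise.",
  "r": 1.0,
  "K": 1.2,
  "a": 2.0,
  "h": 1.0,
  "eps": 0.5,
  "m": 0.2,
  "g": 0.05,
  "delta_b": 0.05,
  "delta_c": 0.05
}
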
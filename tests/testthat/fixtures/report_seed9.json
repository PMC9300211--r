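{
  "schema": "xbnmr-report/1",
  "seed": 9,
  "T_ref": 274,
  "folded_fraction": {
    "melt": 0.499999999812801,
    "namfis": 0.499657940991145,
    "rdc": 0.499630614235776
  },
  "xb": {
    "population": 0.30038458991871,
    "namfis_population": 0.299744049746543,
    "geometry": {
      "distance_A": 3.20036451048939,
      "angle_deg": 145.012787422276
    }
  },
  "melt": {
    "Tm": 273.999999980444,
    "dHm": 23899.9999932953,
    "dSm_TmRoute": 87.2262773540186
  },
  "relative": {
    "K_ratio": 1.31672905908099,
    "ddG_J": -612.162487404736,
    "Tm2": 267.599999992442,
    "n_protons": 10
  },
  "rdc_quality": {
    "Q": 0.00042171925945564,
    "condition_number": 3.73131184061586,
    "best_size": 4
  }
}
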
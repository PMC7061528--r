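{
  "profile": "paper",
  "network": "default",
  "seed": 1,
  "out_dir": "runs/paper",
  "simulation": {
    "t_max": 20000,
    "n_runs": 45,
    "burn_in_frac": 0.1,
    "record_every": 0,
    "axes": ["P53", "ZEB", "OCT4"],
    "bin_width": 5,
    "dispersed_inits": true
  },
  "landscape": {
    "smooth_bw": 1,
    "merge_threshold": 0.5,
    "thresholds": {}
  },
  "kinetics": {
    "delta_core": 1,
    "n_passages": 20,
    "max_events": 5000000000,
    "forward_routes": [
      ["normal", "SC", "CSC", "cancer"],
      ["normal", "premalignant", "cancer"],
      ["normal", "lesion", "hyperplasia", "cancer"]
    ],
    "reverse_routes": [
      ["cancer", "CSC", "SC", "normal"],
      ["cancer", "premalignant", "normal"],
      ["cancer", "hyperplasia", "lesion", "normal"]
    ]
  },
  "sensitivity": {
    "regulations": ["miR200-|ZEB", "OCT4->OCT4", "P53->P53"],
    "scales": [0.8, 1, 1.3, 1.5],
    "t_max": 20000,
    "n_runs": 8
  },
  "synthetic": {
    "n_per_state": 50,
    "noise": 0.4
  }
}
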
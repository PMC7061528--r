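# Configuration file formats

All configuration is JSON (parsed with jsonlite).

## Network file

```json
{
  "omega": 1000,
  "params": {"k": 1, "g0": 50, "lambda_a": 8, "lambda_r": 0.5,
              "h_a": 2, "h_r": 1.875, "omega": 1000},
  "nodes": [
    {"name": "P53", "kind": "protein", "g0": 50, "k": 1},
    {"name": "miR145", "kind": "microRNA", "g0": 50, "k": 1}
  ],
  "regulations": [
    {"source": "P53", "target": "miR145", "sign": "activation",
     "m": 4, "h": 0.00047, "f": 1000, "lambda": 8, "strength_scale": 1}
  ]
}
```

* `omega` — adiabatic parameter; the default unbinding rate is `f = k * omega`.
* `params` — global kinetic defaults; any omitted per-node / per-regulation
  value falls back to these (by regulation sign for `h` and `lambda`).
* `regulations[].m` — multimer order of the binding unit (1, 2 or 4).
* `regulations[].h` — binding rate per multimer; the shipped default network
  derives it from a per-site occupancy threshold (see the methods vignette).
* `regulations[].strength_scale` — dimensionless multiplier on `h`; the knob
  used by the sensitivity module.

`read_network_config("default")` returns the built-in six-node network
without touching the filesystem.

## Run file

Read with `read_run_config()`; missing fields fall back to the profile
defaults of `run_config(profile)`.

```json
{
  "profile": "desk",
  "seed": 1,
  "network": "default",
  "out_dir": "runs/desk1",
  "simulation": {"t_max": 3000, "n_runs": 4, "burn_in_frac": 0.1,
                  "record_every": 0, "axes": ["P53", "ZEB", "OCT4"],
                  "bin_width": 5},
  "landscape": {"smooth_bw": 1, "merge_threshold": 0.5, "thresholds": null},
  "kinetics": {"delta_core": 1, "n_passages": 6, "max_events": 2e8},
  "sensitivity": {"regulations": ["miR200-|ZEB"], "scales": [0.8, 1, 1.5],
                   "t_max": 2000, "n_runs": 3}
}
```

Profiles: `desk` (minutes on one CPU; basin structure retained, barrier
values noisier) and `paper` (hours-scale headline budget).
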
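{
  "omega": 1000,
  "params": {
    "k": 1,
    "g0": 50,
    "lambda_a": 8,
    "lambda_r": 0.5,
    "h_a": 2,
    "h_r": 1.875,
    "omega": 1000
  },
  "nodes": [
    {
      "name": "P53",
      "kind": "protein",
      "g0": 50,
      "k": 1
    },
    {
      "name": "MDM2",
      "kind": "protein",
      "g0": 50,
      "k": 1
    },
    {
      "name": "ZEB",
      "kind": "protein",
      "g0": 50,
      "k": 1
    },
    {
      "name": "OCT4",
      "kind": "protein",
      "g0": 50,
      "k": 1
    },
    {
      "name": "miR145",
      "kind": "microRNA",
      "g0": 50,
      "k": 1
    },
    {
      "name": "miR200",
      "kind": "microRNA",
      "g0": 50,
      "k": 1
    }
  ],
  "regulations": [
    {
      "source": "miR200",
      "target": "ZEB",
      "sign": "repression",
      "m": 4,
      "h": 0.00912242291552636,
      "f": 1000,
      "lambda": 0.5,
      "strength_scale": 1
    },
    {
      "source": "P53",
      "target": "miR200",
      "sign": "activation",
      "m": 4,
      "h": 1.63083025894649e-05,
      "f": 1000,
      "lambda": 8,
      "strength_scale": 1
    },
    {
      "source": "P53",
      "target": "miR145",
      "sign": "activation",
      "m": 4,
      "h": 4.06770135701365e-07,
      "f": 1000,
      "lambda": 8,
      "strength_scale": 1
    },
    {
      "source": "P53",
      "target": "MDM2",
      "sign": "activation",
      "m": 4,
      "h": 1.63083025894649e-05,
      "f": 1000,
      "lambda": 8,
      "strength_scale": 1
    },
    {
      "source": "miR145",
      "target": "ZEB",
      "sign": "repression",
      "m": 4,
      "h": 1.63083025894649e-05,
      "f": 1000,
      "lambda": 0.5,
      "strength_scale": 1
    },
    {
      "source": "miR145",
      "target": "OCT4",
      "sign": "repression",
      "m": 4,
      "h": 7.55763813832095e-07,
      "f": 1000,
      "lambda": 0.5,
      "strength_scale": 1
    },
    {
      "source": "miR145",
      "target": "MDM2",
      "sign": "repression",
      "m": 4,
      "h": 4.33036530095606e-05,
      "f": 1000,
      "lambda": 0.5,
      "strength_scale": 1
    },
    {
      "source": "ZEB",
      "target": "miR200",
      "sign": "repression",
      "m": 4,
      "h": 1.63083025894649e-05,
      "f": 1000,
      "lambda": 0.5,
      "strength_scale": 1
    },
    {
      "source": "ZEB",
      "target": "miR145",
      "sign": "repression",
      "m": 4,
      "h": 0.000158069778322943,
      "f": 1000,
      "lambda": 0.5,
      "strength_scale": 1
    },
    {
      "source": "ZEB",
      "target": "ZEB",
      "sign": "activation",
      "m": 4,
      "h": 9.78400823422133e-05,
      "f": 1000,
      "lambda": 8,
      "strength_scale": 1
    },
    {
      "source": "OCT4",
      "target": "miR200",
      "sign": "activation",
      "m": 4,
      "h": 1.63083025894649e-05,
      "f": 1000,
      "lambda": 8,
      "strength_scale": 1
    },
    {
      "source": "OCT4",
      "target": "miR145",
      "sign": "repression",
      "m": 4,
      "h": 7.55763813832095e-07,
      "f": 1000,
      "lambda": 0.5,
      "strength_scale": 1
    },
    {
      "source": "MDM2",
      "target": "P53",
      "sign": "repression",
      "m": 4,
      "h": 4.06770135701365e-07,
      "f": 1000,
      "lambda": 0.5,
      "strength_scale": 1
    },
    {
      "source": "OCT4",
      "target": "OCT4",
      "sign": "activation",
      "m": 4,
      "h": 7.44371730905451e-06,
      "f": 1000,
      "lambda": 8,
      "strength_scale": 1
    },
    {
      "source": "P53",
      "target": "P53",
      "sign": "activation",
      "m": 4,
      "h": 8.39693592449341e-06,
      "f": 1000,
      "lambda": 8,
      "strength_scale": 1
    },
    {
      "source": "P53",
      "target": "OCT4",
      "sign": "repression",
      "m": 4,
      "h": 2.52050657050316e-08,
      "f": 1000,
      "lambda": 0.5,
      "strength_scale": 1
    }
  ]
}
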
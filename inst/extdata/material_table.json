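{
  "version": "1.0",
  "units": {"E": "MPa", "density": "kg/m3", "ct": "HU"},
  "bone_regimes": [
    {
      "name": "trabecular",
      "ct_interval": [-1000, 500],
      "density_interval": [0, 1000],
      "law": {"coefficient": 0.0004, "exponent": 2.01},
      "poisson": 0.3,
      "printed_E_range": [180, 380]
    },
    {
      "name": "cortical",
      "ct_interval": [501, 1500],
      "density_interval": [1001, 2000],
      "law": {"coefficient": 0.005, "exponent": 2.01},
      "poisson": 0.3,
      "printed_E_range": [11300, 22900]
    }
  ],
  "constants": {
    "dentin":   {"E": 24535,  "poisson": 0.3,   "hu_rule": "<=2000"},
    "enamel":   {"E": 39605,  "poisson": 0.3,   "hu_rule": ">2000"},
    "titanium": {"E": 113800, "poisson": 0.342},
    "bone_uniform": {"E": 10000, "poisson": 0.3}
  },
  "tooth_hu_split": 2000,
  "E_floor": 0.01
}
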
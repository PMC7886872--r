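{
  "seed": 20,
  "phantom": {"n_tumors": 2, "depth": 5, "root_radius": 0.002,
              "asymmetry": 0.8},
  "sim": {"cardiac_period": 1.0, "n_cycles": 4, "dt": 0.002},
  "infusions": [
    {"activity_GBq": 0.5, "injection_velocity": 0.52,
     "radial_offset_fraction": 0.0, "n_particles": 10000},
    {"activity_GBq": 0.2, "injection_velocity": 0.45,
     "radial_offset_fraction": 0.3, "azimuth": 1.57,
     "n_particles": 10000}
  ],
  "noise_sd": 2
}
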
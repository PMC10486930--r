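{
  "seed": 1,
  "synth": {
    "n_stacks_per_group": 5,
    "stack_dim": [48, 48, 48],
    "n_astrocytes": 2,
    "mito_saline": {"enclosed": 2, "external": 8, "border": 1},
    "mito_microbead": {"enclosed": 5, "external": 8, "border": 1},
    "noise_sd": 0,
    "ct": {
      "n_control": 33,
      "n_treated": 39,
      "reactive_fraction": 0.3,
      "fold_change": {"Gulp1": 6, "Lgals3": 23.7},
      "baseline_dct_mean": 5,
      "baseline_dct_sd": 0.85,
      "dropout_prob": 0.05
    },
    "iop": {
      "n_eyes_per_group": 10,
      "baseline_mmHg": 15,
      "amplitude_mmHg": 10,
      "peak_day": 7,
      "noise_sd": 1
    },
    "retina": {
      "n_retinas_per_group": 6,
      "n_fields": 8,
      "density_control": 3500,
      "density_loss_pct": 15,
      "field_area_mm2": 0.04,
      "density_cv": 0.08
    }
  }
}
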
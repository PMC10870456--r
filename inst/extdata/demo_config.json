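{
  "seed": 7,
  "pipeline": {
    "n_pd": 2,
    "n_healthy": 2,
    "targets": [1],
    "repetitions": 2,
    "noise_sd_cm": 0.02,
    "cv": 0.15
  }
}
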
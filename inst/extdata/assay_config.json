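{
  "chis": [0, 0.2, 0.375, 0.6, 0.8, 1],
  "peak_chi": 0.375,
  "peak_factor": 10,
  "end_factor": 2,
  "k0": 0.01,
  "noise_sd": 0.01,
  "seed": 20170609,
  "times": [0, 4, 8, 12, 16, 20, 24, 28, 32, 36, 40, 44, 48, 52, 56, 60, 64, 68, 72, 76, 80, 84, 88, 92, 96, 100, 104, 108, 112, 116, 120]
}
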
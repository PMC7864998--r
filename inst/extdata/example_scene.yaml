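scene:
  height: 128
  width: 128
  mean_rows: [32.0, 68.0, 88.0]
  undulation_amplitude: 5.0
  undulation_periods: 2.0
  n_scans: 10
  seed: 1
graders:
- grading_id: g1
  bias: [0.0, -1.5, 6.0]
  noise_sd: 1.5
  correlation_length: 32
- grading_id: g2
  bias: [0.0, 0.0, -1.5]
  noise_sd: 1.5
  correlation_length: 32
- grading_id: g3
  bias: [0.0, 1.5, -6.0]
  noise_sd: 1.5
  correlation_length: 32
model:
  grading_id: cnn
  weights:
    g1: 0.35
    g2: 0.5
    g3: 0.15
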
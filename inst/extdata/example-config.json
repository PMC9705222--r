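{
  "preset": "realistic",
  "N": 1024,
  "M": 64,
  "seed": 1,
  "snr_db": 50,
  "jitter": 3.141592653589793,
  "depths_n": 31,
  "depths_span": 0.9,
  "mode": "calibrated",
  "k_method": "polynomial",
  "k_degree": 7,
  "z_method": "polynomial",
  "z_degree": 7,
  "log_level": "INFO"
}
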
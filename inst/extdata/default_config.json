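{
  "bucket_width": 0.004,
  "bucket_range": [0.5, 9.0],
  "exclusion": [4.2, 5.2],
  "K": 7,
  "alpha": 0.05,
  "group_sizes": {"healthy": 46, "benign": 25, "malignant": 28}
}
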
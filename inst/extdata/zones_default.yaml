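# Default electrophoretic zone boundaries as fractions of the point axis.
# Half-open [start, end) intervals, 0-based after scaling by n_points.
orientation: albumin_first
zones:
  albumin: [0.05, 0.25]
  alpha1: [0.25, 0.35]
  alpha2: [0.35, 0.48]
  beta1: [0.48, 0.58]
  beta2: [0.58, 0.70]
  gamma: [0.70, 0.98]
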
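trial_id: synthetic-seed42
task: OF
frame_rate: 300.0
surface_labels: []
known_pairs:
- label_a: shoulder_L
  label_b: shoulder_R
  known_distance: 14.0
- label_a: lumbar_L
  label_b: lumbar_R
  known_distance: 14.0
- label_a: hip_L
  label_b: hip_R
  known_distance: 14.0
- label_a: knee_L
  label_b: knee_R
  known_distance: 14.0
- label_a: ankle_L
  label_b: ankle_R
  known_distance: 14.0
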
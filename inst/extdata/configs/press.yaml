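# Press disturbance: 40-fold daily dilution on days 22-31.
regime:
  kind: press
  baseline_fold: 10
  disturbance_fold: 40
  start_day: 22
  duration_days: 10
init:
  prey: 3.6e7
  predator: 4.2e4
n_days: 62
output_dir: presspulse-press
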
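# Press-duration sweep: 2-12 disturbed days at fold 40.
regime:
  kind: press
  baseline_fold: 10
  disturbance_fold: 40
  start_day: 22
  duration_days: 10
init:
  prey: 3.6e7
  predator: 4.2e4
sweep:
  variable: press_duration
  values: [2, 4, 6, 8, 10, 12]
output_dir: presspulse-sweep-press
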
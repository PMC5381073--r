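# Pulse-strength sweep: decade folds 10 .. 1e6 on day 15.
regime:
  kind: pulse
  baseline_fold: 10
  disturbance_fold: 2500
  start_day: 15
init:
  prey: 4.0e6
  predator: 4.0e3
sweep:
  variable: pulse_fold
  values: [10, 100, 1000, 10000, 100000, 1000000]
output_dir: presspulse-sweep-pulse
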
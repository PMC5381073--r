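# Pulse disturbance: a single 2500-fold dilution on day 15.
regime:
  kind: pulse
  baseline_fold: 10
  disturbance_fold: 2500
  start_day: 15
init:
  prey: 4.0e6
  predator: 4.0e3
n_days: 45
output_dir: presspulse-pulse
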
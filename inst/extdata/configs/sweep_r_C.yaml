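# Resource-coupling sweep: r_C 0.007 .. 0.011 under the 2500-fold pulse.
regime:
  kind: pulse
  baseline_fold: 10
  disturbance_fold: 2500
  start_day: 15
init:
  prey: 4.0e6
  predator: 4.0e3
sweep:
  variable: r_C
  values: [0.007, 0.008, 0.009, 0.010, 0.011]
output_dir: presspulse-sweep-rc
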
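# Undisturbed control: tenfold daily dilution throughout.
regime:
  kind: control
  baseline_fold: 10
init:
  prey: 3.6e7
  predator: 4.2e4
n_days: 22
output_dir: presspulse-control
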
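# Synthetic VBGF parameter registry — illustrative values only.
# The published species- and sex-specific growth-curve fits used to
# backtransform ages in real analyses come from external age-and-growth
# studies and must be supplied by the user; these entries exist so the
# packaged example pipeline runs end to end.
parameters:
- species: R. terraenovae
  sex: male
  L_inf: 930.0
  k: 0.45
  t0: -0.9
  source: synthetic illustrative values
- species: R. terraenovae
  sex: female
  L_inf: 980.0
  k: 0.4
  t0: -1.0
  source: synthetic illustrative values
- species: C. acronotus
  sex: male
  L_inf: 1120.0
  k: 0.3
  t0: -1.4
  source: synthetic illustrative values
- species: C. acronotus
  sex: female
  L_inf: 1190.0
  k: 0.27
  t0: -1.5
  source: synthetic illustrative values
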
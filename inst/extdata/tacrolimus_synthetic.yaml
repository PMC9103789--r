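# Synthetic tacrolimus victim configuration: representative values, not a
# published model. clint_hlm and the CYP3A4/CYP3A5 split are placeholders to
# be pinned by calibrate_baseline(); the "other" fraction is kept.
name: tacrolimus
mw: 804.02
fu_plasma: 0.013
bp_ratio: 15
fa: 0.25
ka: 4.48
vss: 18
kp_scalar: 1
clint_hlm: 1000
enzyme_fractions:
  CYP3A4: 0.475
  CYP3A5: 0.475
  other: 0.05
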
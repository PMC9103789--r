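# Schizandrol B compound configuration (perpetrator)
name: SZB
mw: 416.47
logP: 3.380
fu_plasma: 0.084
bp_ratio: 0.785
fa: 0.734
ka: 0.437
peff: 1.0
vss: 2.225
kp_scalar: 1
clint_hlm: 4.5
enzyme_fractions:
  CYP3A4: 0
  CYP3A5: 0
  other: 1
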
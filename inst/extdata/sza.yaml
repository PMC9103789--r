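# Schizandrol A compound configuration (perpetrator)
name: SZA
mw: 432.52
logP: 3.390
fu_plasma: 0.083
bp_ratio: 1.254
fa: 0.500
ka: 0.218
peff: 0.5
vss: 2.516
kp_scalar: 0.5
clint_hlm: 50
enzyme_fractions:
  CYP3A4: 0
  CYP3A5: 0
  other: 1
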
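# Seed H: honeycomb-array hollow origami bundle, 54 helices.
# Growth segments are 126 bp; 36-bp spacer/twister segments introduce a
# right-handed 1.2 deg twist.
name: seed_H
cross_section:
  array_type: honeycomb
  rim_cols: 12
  rim_rows: 6
  pore_cols: 6
  pore_rows: 3
rise: 0.34
twist_rate: 0.03333333333333333   # 1.2 deg / 36 bp
segments:
  - {id: Z1, role: growth,         bp: 126, twist: 0}
  - {id: Z2, role: spacer_twister, bp: 36,  twist: 1.2}
  - {id: Z3, role: growth,         bp: 126, twist: 0}
  - {id: Z4, role: spacer_twister, bp: 36,  twist: 1.2}
  - {id: Z5, role: growth,         bp: 126, twist: 0}
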
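# Seed S: square-array hollow origami bundle, 48 helices.
# Z1/Z3/Z5 are nucleation-and-growth segments (128 bp each); Z2/Z4 are
# spacer/twister segments (32 bp) introducing a right-handed 3.8 deg twist.
name: seed_S
cross_section:
  array_type: square
  rim_cols: 8
  rim_rows: 8
  pore_cols: 4
  pore_rows: 4
rise: 0.34
twist_rate: 0.11875   # 3.8 deg / 32 bp
segments:
  - {id: Z1, role: growth,         bp: 128, twist: 0}
  - {id: Z2, role: spacer_twister, bp: 32,  twist: 3.8}
  - {id: Z3, role: growth,         bp: 128, twist: 0}
  - {id: Z4, role: spacer_twister, bp: 32,  twist: 3.8}
  - {id: Z5, role: growth,         bp: 128, twist: 0}
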
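# Seed S(G): gradient (asymmetric) variant of seed S.
# Z1 grows a uniform square first layer; Z2 spaces and twists the second
# layer by 2.8 deg (face b); Z3 has a trapezoidal cross-section whose tilted
# face a adds delta_theta = 10.9 deg, for a total 13.7 deg.
# The 24-bp spacer length reproduces the 2.8 deg twist at the square-array
# calibration rate; the main design quantity is the stored twist itself.
name: seed_SG
cross_section:
  array_type: square
  rim_cols: 8
  rim_rows: 8
  pore_cols: 4
  pore_rows: 4
  taper:
    delta_theta: 10.9
    tilted_face: a
rise: 0.34
twist_rate: 0.11875
segments:
  - {id: Z1, role: growth,         bp: 128, twist: 0}
  - {id: Z2, role: spacer_twister, bp: 24,  twist: 2.8}
  - {id: Z3, role: growth,         bp: 128, twist: 0}
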
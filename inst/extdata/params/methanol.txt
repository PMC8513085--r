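# All-atom methanol, Amber94-style parameters (charges adjusted to exact
# neutrality). Units as in water.txt. Torsions: vn kcal/mol, n, gamma deg.
SITES 6
C C 0.1450 3.39967 0.1094
H1 H 0.0400 2.47135 0.0157
H2 H 0.0400 2.47135 0.0157
H3 H 0.0400 2.47135 0.0157
O O -0.6830 3.06647 0.2104
HO H 0.4180 0.0 0.0
BONDS 5
C H1 340.0 1.090
C H2 340.0 1.090
C H3 340.0 1.090
C O 320.0 1.410
O HO 553.0 0.960
ANGLES 7
H1 C H2 35.0 109.5
H1 C H3 35.0 109.5
H2 C H3 35.0 109.5
H1 C O 50.0 109.5
H2 C O 50.0 109.5
H3 C O 50.0 109.5
C O HO 55.0 108.5
TORSIONS 3
H1 C O HO 0.167 3 0.0
H2 C O HO 0.167 3 0.0
H3 C O HO 0.167 3 0.0
GEOMETRY
C 0.000000 0.000000 0.000000
H1 1.090000 0.000000 0.000000
H2 -0.363000 0.980000 0.275000
H3 -0.363000 -0.740000 0.680000
O -0.470000 -0.460000 -1.210000
HO -0.400000 0.250000 -1.850000
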
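# TIP3P-compatible flexible water, Amber94-style parameters.
# charges in au; sigma in angstrom; epsilon in kcal/mol
# bonds: k in kcal/mol/A^2, r0 in angstrom; angles: k in kcal/mol/rad^2, deg
SITES 3
O O -0.834 3.15061 0.1521
H1 H 0.417 0.0 0.0
H2 H 0.417 0.0 0.0
BONDS 2
O H1 553.0 0.9572
O H2 553.0 0.9572
ANGLES 1
H1 O H2 100.0 104.52
TORSIONS 0
GEOMETRY
O 0.000000 0.000000 0.000000
H1 0.957200 0.000000 0.000000
H2 -0.239988 0.926627 0.000000
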
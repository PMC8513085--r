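6
QM water + one MM water (angstrom); QM indices in the .qm sidecar
O     0.0000000000     0.0000000000     0.1173000000
H     0.0000000000     0.7572000000    -0.4692000000
H     0.0000000000    -0.7572000000    -0.4692000000
O     3.1000000000     0.2000000000     0.0000000000
H     4.0572000000     0.2000000000     0.0000000000
H     2.8600120000     1.1266270000     0.0000000000
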
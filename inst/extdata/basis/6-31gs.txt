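# 6-31G* (6-31G plus Cartesian d polarization on heavy atoms) for H and O.
ELEM H
S 3
18.7311370 0.03349460
2.8253937 0.23472695
0.6401217 0.81375733
S 1
0.1612778 1.0
ELEM O
S 6
5484.6717000 0.0018311
825.2349500 0.0139501
188.0469600 0.0684451
52.9645000 0.2327143
16.8975700 0.4701930
5.7996353 0.3585209
SP 3
15.5396160 -0.1107775 0.0708743
3.5999336 -0.1480263 0.3397528
1.0137618 1.1307670 0.7271586
SP 1
0.2700058 1.0 1.0
D 1
0.8 1.0
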
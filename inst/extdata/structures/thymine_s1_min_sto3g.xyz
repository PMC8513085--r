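15
thymine S1 (CIS) minimum, CIS/STO-3G (this package), E=-445.50020555
C         2.7038955363       1.0202489753       0.0424655162
C         1.2186960772       0.6913173530       0.0118374343
C         0.2571672436       1.6073797690      -0.0080040710
N        -1.1237795652       1.2493545565      -0.0348988775
C        -1.6088651537      -0.0870140578      -0.0222976861
O        -2.7944173464      -0.3793995962      -0.0283803403
N        -0.5729456887      -1.0552027476      -0.0049568467
C         0.8313691730      -0.7165557931       0.0084001831
O         1.6942355342      -1.7137181829       0.0147195455
H         2.8567353318       2.0941825016       0.0443394549
H         3.2055606749       0.5989428832      -0.8269212284
H         3.1667169284       0.6016992483       0.9344685706
H         0.4520407701       2.6731536592      -0.0076447255
H        -1.8293840041       1.9822875038      -0.0393484779
H        -0.8545455113      -2.0341060724      -0.0022884512
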
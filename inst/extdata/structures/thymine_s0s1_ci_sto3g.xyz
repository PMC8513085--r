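15
thymine S0/S1 intersection, seam-tracked CIS/STO-3G (this package), Eav=-445.44060520 gap=0.000024
C         2.6560528793       1.0335412675       0.0420891175
C         1.1532118773       0.7231178070       0.0135761956
C         0.1971316145       1.6582951346      -0.0094734553
N        -1.1632245003       1.3189754926      -0.0337589564
C        -1.6859433363      -0.0212948581      -0.0243702805
O        -2.8235033202      -0.3204402248      -0.0302050704
N        -0.5534996431      -0.9492651371      -0.0053893383
C         0.7837957789      -0.7218669822       0.0162721196
O         2.2291315858      -2.3410038272       0.0161265468
H         2.8570854281       2.1010802641       0.0442226028
H         3.1640930027       0.6000396586      -0.8189049526
H         3.1280263038       0.6032166925       0.9248313781
H         0.3898460432       2.7304917300      -0.0111991456
H        -1.8740055603       2.0512481922      -0.0400475357
H        -0.8557181532      -1.9335652100      -0.0022792254
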
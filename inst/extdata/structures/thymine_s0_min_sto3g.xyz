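15
thymine S0 minimum, HF/STO-3G (this package), E=-445.67115100
C         2.6907271340       1.0199591500       0.0424084835
C         1.2097980048       0.6933969313       0.0116097244
C         0.2430982111       1.5958277968      -0.0086098687
N        -1.1243229835       1.2578890061      -0.0316643969
C        -1.6001994300      -0.0831379878      -0.0213443865
O        -2.7839604401      -0.3760901634      -0.0281449628
N        -0.5472839781      -1.0373231911      -0.0039566490
C         0.8605036377      -0.7687236492       0.0076205296
O         1.6702589686      -1.6825965944       0.0141433227
H         2.8584424958       2.0914777141       0.0450001946
H         3.1915960787       0.5895721351      -0.8210451603
H         3.1521474100       0.5921202834       0.9288566002
H         0.4420537469       2.6630024568      -0.0096050805
H        -1.8278774594       1.9950025118      -0.0408371299
H        -0.8325013965      -2.0178063995      -0.0029412204
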
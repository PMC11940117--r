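label,x,y,z
Cz,0,0,1
Fpz,0,0.9510565163,0.3090169944
AFz,0,0.8090169944,0.5877852523
Fz,0,0.5877852523,0.8090169944
FCz,0,0.3090169944,0.9510565163
CPz,0,-0.3090169944,0.9510565163
Pz,0,-0.5877852523,0.8090169944
POz,0,-0.8090169944,0.5877852523
Oz,0,-0.9510565163,0.3090169944
Fp1,-0.2938926261,0.9045084972,0.3090169944
AF7,-0.5590169944,0.7694208843,0.3090169944
F7,-0.7694208843,0.5590169944,0.3090169944
FT7,-0.9045084972,0.2938926261,0.3090169944
T7,-0.9510565163,0,0.3090169944
TP7,-0.9045084972,-0.2938926261,0.3090169944
P7,-0.7694208843,-0.5590169944,0.3090169944
PO7,-0.5590169944,-0.7694208843,0.3090169944
O1,-0.2938926261,-0.9045084972,0.3090169944
F3,-0.4330274292,0.6454163629,0.6292256862
C3,-0.5877852523,0,0.8090169944
P3,-0.4330274292,-0.6454163629,0.6292256862
AF3,-0.2942920171,0.8309616198,0.4721175649
FC3,-0.5435233041,0.362291156,0.7571839514
CP3,-0.5435233041,-0.362291156,0.7571839514
PO3,-0.2942920171,-0.8309616198,0.4721175649
Fp2,0.2938926261,0.9045084972,0.3090169944
AF8,0.5590169944,0.7694208843,0.3090169944
F8,0.7694208843,0.5590169944,0.3090169944
FT8,0.9045084972,0.2938926261,0.3090169944
T8,0.9510565163,0,0.3090169944
TP8,0.9045084972,-0.2938926261,0.3090169944
P8,0.7694208843,-0.5590169944,0.3090169944
PO8,0.5590169944,-0.7694208843,0.3090169944
O2,0.2938926261,-0.9045084972,0.3090169944
F4,0.4330274292,0.6454163629,0.6292256862
C4,0.5877852523,0,0.8090169944
P4,0.4330274292,-0.6454163629,0.6292256862
AF4,0.2942920171,0.8309616198,0.4721175649
FC4,0.5435233041,0.362291156,0.7571839514
CP4,0.5435233041,-0.362291156,0.7571839514
PO4,0.2942920171,-0.8309616198,0.4721175649
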
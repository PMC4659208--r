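id,length_mm,diameter_mm
RICA,177,4.0
LICA,177,4.0
RVA,148,2.72
LVA,148,2.72
BA,28.6,3.24
RA1,12,2.34
LA1,12,2.34
ACoA,3,1.48
RP1,5,2.14
LP1,5,2.14
RPCoA,15,1.46
LPCoA,15,1.46
RMCA,119,2.86
LMCA,119,2.86
RA2,103,2.4
LA2,103,2.4
RP2,86,2.1
LP2,86,2.1
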
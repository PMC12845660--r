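compound_id,rpf
PFBA,0.05
PFPeA,0.03
PFHxA,0.01
PFHpA,0.505
PFOA,1
PFNA,10
PFBS,0.001
PFHxS,0.6
PFOS,2
FTS_6_2,0.02
TFA,0.002
PFPrA,0.03
TFMS,0.001
ADONA,0.06
9H-PFNA,0.1
7H-PFHpA,0.1
Flupropanate,0.002
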
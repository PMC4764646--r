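# Genes identified as candidate CRC susceptibility genes in mouse
# Sleeping-Beauty transposon screens. Illustrative reconstruction.
LRP6
APC
PTEN
SMAD4
RSPO2
TCF12
STAG1
ZNF292
RASGRF1
BMPR1A
CTNNB1
MYH9
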
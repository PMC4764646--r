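# Genes recurrently mutated somatically in colorectal adenocarcinoma
# (candidate CRC driver genes). Illustrative reconstruction: contains the
# drivers the triage logic must recognize plus field-standard members.
APC
TP53
KRAS
PIK3CA
SMAD4
FBXW7
TCF7L2
SOX9
ARID1A
BRAF
ACVR2A
AMER1
PTPN12
MSH6
TTN
ATM
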
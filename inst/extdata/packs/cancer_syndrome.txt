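# Genes predisposing to other cancer types or causing recessive cancer
# syndromes when biallelic. Illustrative reconstruction (synthetic subset).
ATM
BLM
BRIP1
BRCA1
BRCA2
CHEK2
ERCC3
FANCA
FANCC
NBN
PALB2
RECQL4
TP53
WRN
XPA
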
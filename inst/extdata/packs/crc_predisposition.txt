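# Known colorectal-cancer predisposition genes (Mendelian CRC syndromes):
# mismatch-repair genes, polyposis genes and polymerase-proofreading genes.
# Illustrative reconstruction for demonstration and testing; supply your
# own curated list for real analyses.
MLH1
MSH2
MSH6
PMS2
EPCAM
APC
MUTYH
NTHL1
POLE
POLD1
SMAD4
BMPR1A
STK11
PTEN
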
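# Union of genes in cancer-related KEGG pathways: WNT signaling,
# TGF-beta signaling, mismatch repair, base excision repair, nucleotide
# excision repair, non-homologous end-joining, Fanconi anemia, and
# pathways in cancer. Illustrative reconstruction (synthetic subset);
# pathway membership drifts between database releases.
LRP5
LRP6
WNT1
WNT3A
FZD1
CTNNB1
APC
AXIN1
AXIN2
GSK3B
TCF7L2
DKK1
TGFB1
TGFBR1
TGFBR2
SMAD2
SMAD3
SMAD4
MLH1
MSH2
MSH6
PMS2
MUTYH
NTHL1
OGG1
ERCC1
ERCC2
ERCC3
XPA
XPC
XRCC4
XRCC5
XRCC6
PRKDC
LIG4
FANCA
FANCC
FANCD2
BRCA1
BRCA2
TP53
KRAS
PIK3CA
EGFR
MYC
CCND1
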
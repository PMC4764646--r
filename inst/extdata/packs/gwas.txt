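# Genes at loci identified in colorectal-cancer genome-wide association
# studies. Illustrative reconstruction (synthetic subset).
GREM1
SMAD7
RHPN2
BMP2
BMP4
CDH1
EIF3H
POU5F1B
CCAT2
LAMA5
CRAC1
COLCA1
COLCA2
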
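# Genes tolerant of loss-of-function variation in healthy populations,
# excluded from candidacy. Illustrative reconstruction (synthetic subset).
OR4C11
OR2T33
OR10G4
OR51A2
KRTAP5-5
KRTAP10-6
MUC17
FLG2
TCHH
CDC27
HRNR
PRB4
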
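# Cancer driver genes recurrently mutated in cutaneous melanoma
BRAF
NRAS
NF1
KIT
TP53
CDKN2A
PTEN
PPP6C
ARID2
IDH1
RAC1
MAP2K1
DDX3X
RB1
KMT2D
COL5A1
CTNNB1
MECOM
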
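# Synthetic stand-in SASP reference list (one protein per line).
# Illustrative set of proteins commonly reported in senescence-associated
# secretory phenotypes of epithelial cells; replace with your own atlas
# export for real analyses.
CLU
IGFBP7
IGFBP3
TIMP1
TIMP2
SERPINE1
GDF15
IL6
CXCL8
MMP1
MMP3
STC1
CST3
B2M
LGALS3
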
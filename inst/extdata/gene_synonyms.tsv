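# canonical	synonyms (|-separated)
CHK2	CHEK2|CHK-2
HER2	ERBB2|NEU
TP53	p53
KRAS	K-RAS
BRCA1	BRCA-1
BRCA2	BRCA-2
VEGF	VEGFA
NTRK1	TRKA
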
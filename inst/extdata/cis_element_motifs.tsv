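name	category	consensus
CGTCA-motif	hormone	CGTCA
TGACG-motif	hormone	TGACG
ABRE	hormone	ACGTG
TGA-box	hormone	TGACGTAA
AuxRR-core	hormone	GGTCCAT
GARE-motif	hormone	TCTGTTG
P-box	hormone	CCTTTTG
TATC-box	hormone	TATCCCA
TCA-element	hormone	CCATCTTTTT
LTR	abiotic_stress	CCGAAA
MBS	abiotic_stress	CAACTG
ARE	abiotic_stress	AAACCA
WUN-motif	abiotic_stress	AAATTTCCT
G-box	light	CACGTG
Box-4	light	ATTAAT
GT1-motif	light	GGTTAA
CCAAT-box	development	CAACGG
O2-site	development	GATGAYRTGR
RY-element	development	CATGCATG
motif-I	development	AACGTGT
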
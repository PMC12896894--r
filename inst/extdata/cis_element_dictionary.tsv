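name	pattern	category	subcategory
ABRE	ACGTG	phytohormone	ABA
ABRE3a	TACGTG	phytohormone	ABA
ABRE4	CACGTA	phytohormone	ABA
CGTCA-motif	CGTCA	phytohormone	MeJA
TGACG-motif	TGACG	phytohormone	MeJA
TCA-element	CCATCTTTTT	phytohormone	SA
TCA	TCAGAAGAGG	phytohormone	SA
ERE	ATTTTAAA	phytohormone	ethylene
GARE-motif	TCTGTTG	phytohormone	gibberellin
P-box	CCTTTTG	phytohormone	gibberellin
TGA-element	AACGAC	phytohormone	auxin
AuxRR-core	GGTCCAT	phytohormone	auxin
CAT-box	GCCACT	growth_development	meristem expression
as-1	TGACGTCA	growth_development	shoot expression
W box	TTGACC	growth_development	senescence expression
GCN4_motif	TGAGTCA	growth_development	endosperm expression
AAGAA-motif	GAAAGAA	growth_development	endosperm expression
HD-Zip 1	CAATWATTG	growth_development	palisade mesophyll differentiation
MBS	CAACTG	stress	drought
LTR	CCGAAA	stress	low temperature
DRE	GCCGAC	stress	dehydration
WUN-motif	AAATTTCCT	stress	wounding
MYB	CAACAG	stress	drought/salt/cold
MYC	CATTTG	stress	drought/salt/cold
Box 4	ATTAAT	light	light response
G-box	CACGTT	light	light response
GT1-motif	GGTTAA	light	light response
TCT-motif	TCTTAC	light	light response
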
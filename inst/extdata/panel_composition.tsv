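# Cancer-pathway knockout panel composition: per targeted gene, the number of
# gRNAs designed and the number of validated knockout lines per parental
# background (RPE1, MCF10A, RPTec).
gene	chromosome	n_grna	RPE1	MCF10A	RPTec	core_pathway
APC	5	12	2	3	1	APC Signaling Pathway
ARID1A	1	6	2	2	0	Chromatin Modification
ATM	11	6	2	0	2	DNA Damage Control
ATRX	X	12	0	3	1	Chromatin Modification
BRCA2	13	6	0	0	0	DNA Damage Control
CDKN2A	9	6	1	0	3	Cell Cycle/Apoptosis
CDKN2C	1	6	2	2	0	Cell Cycle/Apoptosis
DAXX	6	6	0	3	0	Chromatin Modification; Cell Cycle/Apoptosis
EZH2	7	6	3	3	2	Chromatin Modification
FBXW7	4	6	0	0	0	NOTCH Signaling Pathway
KMT2D	12	6	1	1	0	Chromatin Modification
MLH1	3	6	0	2	1	DNA Damage Control
MSH2	2	6	3	2	2	DNA Damage Control
MSH6	2	6	3	1	3	DNA Damage Control
NF1	17	6	1	2	0	RAS Signaling Pathway
NOTCH1	9	6	3	2	3	NOTCH Signaling Pathway
PTCH1	9	6	2	2	0	Hedgehog Signaling Pathway
PTEN	10	6	2	1	3	PI3K Pathway Signaling
SMARCB1	22	6	0	0	0	Chromatin Modification
STAG2	X	6	3	3	3	DNA Damage Control
TET2	4	6	3	3	0	Chromatin Modification
TP53	17	6	3	2	3	Cell Cycle/Apoptosis; DNA Damage Control
MTAP	9	6	0	0	0	Control and Passenger Target
TK1	9	6	0	0	0	Control
HPRT	X	6	0	0	0	Control
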
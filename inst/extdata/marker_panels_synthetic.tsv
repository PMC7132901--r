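category	gene
osteogenic	RUNX2
osteogenic	SP7
osteogenic	ALPL
osteogenic	COL1A1
osteogenic	COL1A2
osteogenic	SPARC
osteogenic	SPP1
osteogenic	IBSP
osteogenic	BGLAP
osteogenic	OMD
osteogenic	CDH11
osteogenic	SATB2
osteogenic	MSX2
osteogenic	DLX5
osteogenic	TNFRSF11B
osteogenic	PHEX
osteogenic	MEPE
osteogenic	COL11A1
osteogenic	FBN2
osteogenic	VDR
chondrogenic	SOX9
chondrogenic	SOX5
chondrogenic	SOX6
chondrogenic	ACAN
chondrogenic	COL2A1
chondrogenic	COL9A1
chondrogenic	COL9A2
chondrogenic	COL11A2
chondrogenic	COMP
chondrogenic	HAPLN1
chondrogenic	WWP2
chondrogenic	MIA
chondrogenic	CHAD
chondrogenic	MATN3
chondrogenic	EPYC
chondrogenic	COL10A1
chondrogenic	CRTAC1
chondrogenic	SNORC
chondrogenic	SCRG1
chondrogenic	FMOD
adipogenic	PPARG
adipogenic	CEBPA
adipogenic	CEBPB
adipogenic	ADIPOQ
adipogenic	LPL
adipogenic	FABP4
adipogenic	PLIN1
adipogenic	LEP
adipogenic	CD36
adipogenic	LIPE
adipogenic	PNPLA2
adipogenic	CIDEC
adipogenic	AGPAT2
adipogenic	SLC2A4
adipogenic	NR1H3
adipogenic	SREBF1
adipogenic	FASN
adipogenic	GPD1
adipogenic	APOE
adipogenic	RETN
myogenic	MYOD1
myogenic	MYF5
myogenic	MYOG
myogenic	DES
myogenic	MYH3
myogenic	MYH8
myogenic	ACTA1
myogenic	ACTA2
myogenic	TNNT1
myogenic	TNNT2
myogenic	TNNC1
myogenic	MYL1
myogenic	CKM
myogenic	TTN
myogenic	PAX7
myogenic	SIX1
myogenic	MEF2C
myogenic	CAV3
myogenic	DMD
myogenic	TPM1
neurogenic	SOX2
neurogenic	NES
neurogenic	TUBB3
neurogenic	MAP2
neurogenic	ENO2
neurogenic	NEFL
neurogenic	NEFM
neurogenic	GFAP
neurogenic	NCAM1
neurogenic	SYP
neurogenic	DCX
neurogenic	PAX6
neurogenic	ASCL1
neurogenic	NEUROD1
neurogenic	NTRK2
neurogenic	S100B
neurogenic	MBP
neurogenic	OLIG2
neurogenic	GAP43
neurogenic	STMN2
housekeeping	ACTB
housekeeping	GAPDH
housekeeping	B2M
housekeeping	TUBB
housekeeping	RPL13A
housekeeping	RPS18
housekeeping	UBC
housekeeping	PPIA
housekeeping	PGK1
housekeeping	HPRT1
housekeeping	TBP
housekeeping	GUSB
housekeeping	SDHA
housekeeping	YWHAZ
housekeeping	RPLP0
housekeeping	EEF1A1
housekeeping	POLR2A
housekeeping	TFRC
housekeeping	HMBS
housekeeping	PSMB4
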
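study	marker	phenotype	WT	HET	HOM
UK	SNP	case	3	6	15
UK	SNP	control	25	67	5
UK	L1	case	3	6	15
UK	L1	control	28	67	2
FIN	SNP	case	0	7	42
FIN	SNP	control	26	51	12
FIN	L1	case	0	7	42
FIN	L1	control	28	51	10
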
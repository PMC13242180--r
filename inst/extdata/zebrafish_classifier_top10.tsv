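Trimming	Mapping	Counting	Normalization	Rank F1	Rank NMI	Sum	Rank DGE	Rank
Bbduk	HiSat2	StringTie	FPKM	1	1	2	25	1
Trimmomatic	HiSat2	StringTie	TPM	2	2	4	58	2
Trimmomatic	STAR	StringTie	FPKM	3	3	6	72	3
Trimmomatic	STAR	StringTie	TPM	4	4	8	86	4
Trimmomatic	TopHat2	HTSeq_U	TMM	5	5	10	31	5
Trimmomatic	TopHat2	StringTie	TPM	6	6	12	6	6
Trimmomatic	HiSat2	StringTie	FPKM	11	7	18	50	7
Trimmomatic	TopHat2	HTSeq_IN	RLE	12	8	20	16	8
Trimmomatic	TopHat2	StringTie	FPKM	13	9	22	71	9
Trimmomatic	HiSat2	HTSeq_U	TMM	19	12	31	30	10
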
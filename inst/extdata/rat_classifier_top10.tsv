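Trimming	Mapping	Counting	Normalization	Rank F1	Rank NMI	Sum	Rank DGE	Rank
Trimmomatic	TopHat2	StringTie	Coverage	7	1	8	63	1
Bbduk	STAR	StringTie	FPKM	12	4	16	75	2
Bbduk	TopHat2	StringTie	FPKM	8	8	16	77	3
Cutadapt	TopHat2	StringTie	Coverage	1	15	16	81	4
Cutadapt	TopHat2	StringTie	FPKM	5	12	17	38	5
Bbduk	STAR	StringTie	TPM	4	14	18	33	6
Trimmomatic	STAR	StringTie	Coverage	13	5	18	33	7
Bbduk	STAR	StringTie	Coverage	17	9	26	45	8
Cutadapt	STAR	StringTie	Coverage	20	6	26	60	9
Cutadapt	HiSat2	StringTie	FPKM	6	21	27	53	10
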
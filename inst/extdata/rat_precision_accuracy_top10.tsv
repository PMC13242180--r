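Trimming	Mapping	Counting	Normalization	Precision	Accuracy	Sum	Rank
Bbduk	TopHat2	StringTie	TPM	15.5	25	40.5	1
Cutadapt	TopHat2	StringTie	Coverage	23	19	42	2
Cutadapt	TopHat2	StringTie	TPM	16.5	26	42.5	3
Cutadapt	TopHat2	StringTie	FPKM	10.5	33	43.5	4
Trimmomatic	TopHat2	StringTie	Coverage	25.5	19	44.5	5
Bbduk	TopHat2	StringTie	Coverage	26	19	45	6
Bbduk	TopHat2	StringTie	FPKM	12	33	45	7
Trimmomatic	TopHat2	StringTie	FPKM	14	33	47	8
Bbduk	STAR	StringTie	Coverage	20	28	48	9
Cutadapt	STAR	StringTie	TPM	15	33	48	10
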
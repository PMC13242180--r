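Trimming	Mapping	Counting	Normalization	Rank F1	Rank NMI	Sum	Rank DGE	Rank
Cutadapt	STAR	StringTie	Coverage	1	1	2	10	1
Bbduk	TopHat2	Cufflinks	FPKM	2	2	4	4	2
Bbduk	HiSat2	HTSeq_U	RLE	2	2	4	6	3
Trimmomatic	TopHat2	HTSeq_U	TMM	2	2	4	8	4
Cutadapt	STAR	HTSeq_IN	RLE	2	2	4	12	5
Cutadapt	STAR	HTSeq_IN	TMM	2	2	4	12	6
Cutadapt	TopHat2	StringTie	FPKM	3	3	6	8	7
Bbduk	TopHat2	StringTie	FPKM	3	3	6	11	8
Trimmomatic	TopHat2	HTSeq_IN	RLE	3	3	6	13	9
Bbduk	STAR	StringTie	Coverage	3	5	8	9	10
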
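##gff-version 3
1	toy	gene	15000	17000	.	+	.	ID=GENE_A;Name=TFA
1	toy	gene	25001	27000	.	-	.	ID=GENE_B;Name=GB
1	toy	gene	44000	46000	.	+	.	ID=GENE_C;Name=GC
1	toy	gene	95000	96000	.	-	.	ID=GENE_D;Name=TFD
2	toy	gene	9000	11000	.	+	.	ID=GENE_E;Name=GE
2	toy	gene	500000	502000	.	+	.	ID=GENE_F;Name=GF
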
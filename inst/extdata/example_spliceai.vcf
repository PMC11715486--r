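##fileformat=VCFv4.2
##INFO=<ID=SpliceAI,Number=.,Type=String,Description="SpliceAIv1.3 variant annotation. These include delta scores (DS) and delta positions (DP) for acceptor gain (AG), acceptor loss (AL), donor gain (DG), and donor loss (DL). Format: ALLELE|SYMBOL|DS_AG|DS_AL|DS_DG|DS_DL|DP_AG|DP_AL|DP_DG|DP_DL">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO
17	7676381	.	C	A	.	.	SpliceAI=A|TP53|0.03|0.01|0.85|0.42|-12|28|16|16
17	7675994	.	G	T	.	.	SpliceAI=T|TP53|0.00|0.67|0.02|0.61|-40|2|-40|2
17	7674945	.	G	A	.	.	SpliceAI=A|TP53|0.11|0.04|0.00|0.01|-7|-50|31|-50
17	7673767	.	C	T	.	.	.
17	7673550	.	A	C,G	.	.	SpliceAI=C|TP53|0.92|0.05|0.01|0.03|-2|14|-2|33,G|TP53|0.88|0.04|0.02|0.03|-2|14|-2|33
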
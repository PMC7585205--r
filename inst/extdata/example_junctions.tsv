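chrom	donor	acceptor	strand	support	source
chr1	200	300	+	12	tophat
chr1	200	300	+	9	star
chr1	400	500	+	6	tophat
chr1	400	500	+	4	mapsplice
chr1	2300	2100	-	3	star
chr1	2300	2100	-	4	mapsplice
chr1	900	1200	+	50	star
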
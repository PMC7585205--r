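chr1	flsplice	exon	101	200	.	+	.	gene_id "g1"; transcript_id "g1.t1";
chr1	flsplice	exon	301	400	.	+	.	gene_id "g1"; transcript_id "g1.t1";
chr1	flsplice	exon	501	600	.	+	.	gene_id "g1"; transcript_id "g1.t1";
chr1	flsplice	exon	101	400	.	+	.	gene_id "g1"; transcript_id "g1.t2";
chr1	flsplice	exon	501	600	.	+	.	gene_id "g1"; transcript_id "g1.t2";
chr1	flsplice	exon	2001	2100	.	-	.	gene_id "g2"; transcript_id "g2.t1";
chr1	flsplice	exon	2301	2400	.	-	.	gene_id "g2"; transcript_id "g2.t1";
chr1	flsplice	exon	2001	2100	.	-	.	gene_id "g2"; transcript_id "g2.t2";
chr1	flsplice	exon	2341	2400	.	-	.	gene_id "g2"; transcript_id "g2.t2";
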
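chr1	toy	transcript	10001	20000	.	+	.	gene_id "g1"; transcript_id "t1";
chr1	toy	exon	10001	10500	.	+	.	gene_id "g1"; transcript_id "t1";
chr1	toy	five_prime_utr	10001	10100	.	+	.	gene_id "g1"; transcript_id "t1";
chr1	toy	exon	14001	14500	.	+	.	gene_id "g1"; transcript_id "t1";
chr1	toy	exon	19501	20000	.	+	.	gene_id "g1"; transcript_id "t1";
chr1	toy	three_prime_utr	19801	20000	.	+	.	gene_id "g1"; transcript_id "t1";
chr1	toy	transcript	30001	40000	.	-	.	gene_id "g2"; transcript_id "t2";
chr1	toy	exon	30001	30400	.	-	.	gene_id "g2"; transcript_id "t2";
chr1	toy	three_prime_utr	30001	30100	.	-	.	gene_id "g2"; transcript_id "t2";
chr1	toy	exon	39501	40000	.	-	.	gene_id "g2"; transcript_id "t2";
chr1	toy	five_prime_utr	39901	40000	.	-	.	gene_id "g2"; transcript_id "t2";
chr2	toy	transcript	5001	8000	.	+	.	gene_id "g3"; transcript_id "t3";
chr2	toy	exon	5001	8000	.	+	.	gene_id "g3"; transcript_id "t3";
chr2	toy	five_prime_utr	5001	5100	.	+	.	gene_id "g3"; transcript_id "t3";
chr2	toy	three_prime_utr	7901	8000	.	+	.	gene_id "g3"; transcript_id "t3";
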
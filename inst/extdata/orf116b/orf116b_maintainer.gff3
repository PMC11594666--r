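##gff-version 3
##sequence-region orf116b_locus_maintainer 1 4454
orf116b_locus_maintainer	mitocms	region	1	4454	.	+	.	ID=region:orf116b_locus_maintainer;Is_circular=true
orf116b_locus_maintainer	mitocms	gene	601	1155	.	+	.	ID=gene:rpl5;Name=rpl5;category=protein_coding;start_codon=ATG;copies=1
orf116b_locus_maintainer	mitocms	CDS	601	1155	.	+	.	ID=gene:rpl5.exon1;Parent=gene:rpl5
orf116b_locus_maintainer	mitocms	gene	1556	2554	.	+	.	ID=gene:rpl2;Name=rpl2;category=protein_coding;start_codon=ATG;copies=1
orf116b_locus_maintainer	mitocms	CDS	1556	2554	.	+	.	ID=gene:rpl2.exon1;Parent=gene:rpl2
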
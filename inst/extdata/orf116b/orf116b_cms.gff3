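##gff-version 3
##sequence-region orf116b_locus_cms 1 4880
orf116b_locus_cms	mitocms	region	1	4880	.	+	.	ID=region:orf116b_locus_cms;Is_circular=true
orf116b_locus_cms	mitocms	gene	601	1155	.	+	.	ID=gene:rpl5;Name=rpl5;category=protein_coding;start_codon=ATG;copies=1
orf116b_locus_cms	mitocms	CDS	601	1155	.	+	.	ID=gene:rpl5.exon1;Parent=gene:rpl5
orf116b_locus_cms	mitocms	gene	1343	1693	.	+	.	ID=gene:orf116;Name=orf116;category=ORF;start_codon=ATG;copies=1
orf116b_locus_cms	mitocms	open_reading_frame	1343	1693	.	+	.	ID=gene:orf116.exon1;Parent=gene:orf116
orf116b_locus_cms	mitocms	gene	1653	2651	.	+	.	ID=gene:rpl2;Name=rpl2;category=protein_coding;start_codon=ATG;copies=1
orf116b_locus_cms	mitocms	CDS	1653	2651	.	+	.	ID=gene:rpl2.exon1;Parent=gene:rpl2
orf116b_locus_cms	mitocms	gene	3855	4166	.	+	.	ID=gene:orf103;Name=orf103;category=ORF;start_codon=ATG;copies=1
orf116b_locus_cms	mitocms	open_reading_frame	3855	4166	.	+	.	ID=gene:orf103.exon1;Parent=gene:orf103
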
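##gff-version 3
##sequence-region chr_edc 1 20000
chr_edc	synthetic	gene	1000	1500	.	+	.	ID=PGLYRP3
chr_edc	synthetic	gene	3000	3800	.	+	.	ID=EDWM
chr_edc	synthetic	gene	5000	7200	.	+	.	ID=EDCRP
chr_edc	synthetic	exon	5000	5150	.	+	.	ID=EDCRP.e1;Parent=EDCRP
chr_edc	synthetic	exon	5800	7200	.	+	.	ID=EDCRP.e2;Parent=EDCRP
chr_edc	synthetic	CDS	5850	7100	.	+	0	ID=EDCRP.cds;Parent=EDCRP
chr_edc	synthetic	gene	9000	9900	.	+	.	ID=LOR1
chr_edc	synthetic	gene	11000	11900	.	+	.	ID=LOR2
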
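##gff-version 3
g	toyfam	gene	1	62	.	+	.	ID=g
g	toyfam	mRNA	9	55	.	+	.	ID=c1;Parent=g
g	toyfam	CDS	9	12	.	+	0	ID=c1.cds1;Parent=c1
g	toyfam	CDS	25	36	.	+	0	ID=c1.cds2;Parent=c1
g	toyfam	CDS	51	55	.	+	0	ID=c1.cds3;Parent=c1
g	toyfam	mRNA	4	59	.	+	.	ID=c2;Parent=g
g	toyfam	CDS	4	12	.	+	0	ID=c2.cds1;Parent=c2
g	toyfam	CDS	25	30	.	+	0	ID=c2.cds2;Parent=c2
g	toyfam	CDS	41	46	.	+	0	ID=c2.cds3;Parent=c2
g	toyfam	CDS	51	59	.	+	0	ID=c2.cds4;Parent=c2
h	toyfam	gene	1	60	.	+	.	ID=h
h	toyfam	mRNA	7	55	.	+	.	ID=c3;Parent=h
h	toyfam	CDS	7	10	.	+	0	ID=c3.cds1;Parent=c3
h	toyfam	CDS	23	28	.	+	0	ID=c3.cds2;Parent=c3
h	toyfam	CDS	35	40	.	+	0	ID=c3.cds3;Parent=c3
h	toyfam	CDS	51	55	.	+	0	ID=c3.cds4;Parent=c3
h	toyfam	mRNA	23	59	.	+	.	ID=c4;Parent=h
h	toyfam	CDS	23	28	.	+	0	ID=c4.cds1;Parent=c4
h	toyfam	CDS	35	40	.	+	0	ID=c4.cds2;Parent=c4
h	toyfam	CDS	51	59	.	+	0	ID=c4.cds3;Parent=c4
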
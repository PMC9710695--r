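cds_id	gene_id	block_index	cds_start	cds_end	gene_start	gene_end	pid
c3	g	1	1	4	9	12	1
c3	g	2	5	16	25	36	1
c3	g	3	17	21	51	55	1
c4	g	1	1	12	25	36	1
c4	g	2	13	21	51	59	1
c1	h	1	1	4	7	10	1
c1	h	2	5	10	23	28	1
c1	h	3	11	16	35	40	1
c1	h	4	17	21	51	55	1
c2	h	1	1	9			
c2	h	2	10	15	23	28	1
c2	h	3	16	21	43	48	1
c2	h	4	22	30	51	59	1
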
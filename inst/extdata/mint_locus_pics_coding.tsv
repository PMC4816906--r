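region	length	pics_outgroup	pics_ingroup	pct_outgroup	pct_ingroup
psbA	1056	0	2	0.00	0.19
matK	1530	14	5	0.92	0.33
psbK	186	1	0	0.54	0.00
atpA	1524	5	1	0.33	0.07
atpF Exon1	411	1	0	0.24	0.00
atpI	744	1	0	0.13	0.00
rps2	711	1	0	0.14	0.00
rpoC2	4083	16	3	0.39	0.07
rpoC1 Exon1	1635	1	0	0.06	0.00
rpoC1 Exon2	435	1	0	0.23	0.00
rpoB	3213	4	0	0.12	0.00
psbD	1062	4	0	0.38	0.00
psbC	1422	3	1	0.21	0.07
psaB	2205	6	0	0.27	0.00
psaA	2253	2	0	0.09	0.00
rps4	606	1	0	0.17	0.00
ndhJ	477	3	0	0.63	0.00
ndhK	678	3	0	0.44	0.00
atpE	402	2	0	0.50	0.00
atpB	1497	4	0	0.27	0.00
rbcL	1446	12	6	0.83	0.41
accD	1467	3	0	0.20	0.00
ycf4	555	2	0	0.36	0.00
cemA	690	2	1	0.29	0.14
petA	963	2	1	0.21	0.10
rpl33	201	1	0	0.50	0.00
rpl20	387	2	0	0.52	0.00
psbB	1527	9	0	0.59	0.00
petB Exon2	651	2	1	0.31	0.15
rpoA	1014	3	1	0.30	0.10
rpl36	114	2	0	1.75	0.00
rps8	414	1	0	0.24	0.00
rpl14	369	2	0	0.54	0.00
rpl16 Exon1	393	3	0	0.76	0.00
rps3	663	3	0	0.45	0.00
rpl22	465	1	1	0.22	0.22
rps19	279	6	0	2.15	0.00
rpl2 Exon1	434	1	0	0.23	0.00
ycf2	6849	5	2	0.07	0.03
ndhB Exon1	756	1	0	0.13	0.00
rps7	468	2	1	0.43	0.21
rrn23	2811	1	0	0.04	0.00
ndhF	2229	16	0	0.72	0.00
rpl32	177	2	0	1.13	0.00
ccsA	970	3	2	0.31	0.21
ndhD	1521	11	1	0.72	0.07
psaC	244	1	0	0.41	0.00
ndhE	306	1	2	0.33	0.65
ndhG	531	1	0	0.19	0.00
ndhI	507	2	0	0.39	0.00
ndhA Exon1	539	3	0	0.56	0.00
ndhA Exon2	553	3	1	0.54	0.18
ycf1 SSC	4487	43	11	0.96	0.25
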
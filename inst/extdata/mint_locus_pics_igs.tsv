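region	length	pics_outgroup	pics_ingroup	pct_outgroup	pct_ingroup
trnH-GUG-psbA	323	8	1	2.48	0.31
psbA-trnK-UUU	244	2	0	0.82	0.00
trnK-UUU-rps16	643	5	0	0.78	0.00
rps16-trnQ-UUG	828	10	1	1.21	0.12
psbK-psbI	374	7	0	1.87	0.00
psbI-trnS-GCU	121	1	1	0.83	0.83
trnS-GCU-trnG-UCC	694	5	1	0.72	0.14
trnG-UCC-trnR-UCU	160	2	0	1.25	0.00
atpF-atpH	365	5	1	1.37	0.27
atpH-atpI	975	8	5	0.82	0.51
rps2-rpoC2	337	2	0	0.59	0.00
rpoC2-rpoC1	154	1	0	0.65	0.00
rpoB-trnC-GCA	1098	6	4	0.55	0.36
trnC-GCA-petN	436	4	0	0.92	0.00
petN-psbM	509	5	2	0.98	0.39
psbM-trnD-GUC	518	3	0	0.58	0.00
trnE-UUC-trnT-GGU	570	7	1	1.23	0.18
trnT-GGU-psbD	1075	8	1	0.74	0.09
psbC-trnS-UGA	232	3	1	1.29	0.43
trnS-UGA-psbZ	328	3	0	0.91	0.00
psbZ-trnG-GCC	224	2	0	0.89	0.00
trnG-GCC-trnfM-CAU	149	1	0	0.67	0.00
psaA-ycf3	730	7	0	0.96	0.00
ycf3-trnS-GGA	316	2	2	0.63	0.63
trnS-GGA-rps4	162	1	0	0.62	0.00
rps4-trnT-UGU	385	3	1	0.78	0.26
trnT-UGU-trnL-UAA	690	9	0	1.30	0.00
trnL-UAA-trnF-GAA	295	3	0	1.02	0.00
trnF-GAA-ndhJ	658	0	1	0.00	0.15
ndhC-trnV-UAC	944	5	0	0.53	0.00
trnV-UAC-trnM-CAU	188	1	0	0.53	0.00
trnM-CAU-atpE	213	2	0	0.94	0.00
atpB-rbcL	801	1	1	0.12	0.12
rbcL-accD	707	7	2	0.99	0.28
accD-psaI	397	1	1	0.25	0.25
psaI-ycf4	434	7	0	1.61	0.00
ycf4-cemA	306	5	1	1.63	0.33
cemA-petA	217	1	1	0.46	0.46
petA-psbJ	1059	9	3	0.85	0.28
psbE-petL	915	6	1	0.66	0.11
petL-petG	174	2	0	1.15	0.00
petG-trnW-CCA	125	1	0	0.80	0.00
trnP-UGG-psaJ	270	2	1	0.74	0.37
psaJ-rpl33	478	5	0	1.05	0.00
rpl33-rps18	146	0	1	0.00	0.68
rps18-rpl20	216	5	0	2.31	0.00
rpl20-rps12	739	10	0	1.35	0.00
psbB-psbT	184	1	1	0.54	0.54
psbH-petB	124	1	0	0.81	0.00
petB-petD	194	1	0	0.52	0.00
infA-rps8	123	1	0	0.81	0.00
rps8-rpl14	173	3	0	1.73	0.00
rpl14-rpl16	126	1	0	0.79	0.00
rpl16-rps3	141	1	1	0.71	0.71
rps12-3'end-trnV-GAC	1448	3	0	0.21	0.00
trnA-UGC-rrn23	199	1	0	0.50	0.00
rrn4.5-rrn5	224	2	1	0.89	0.45
rrn5-trnR-ACG	234	2	1	0.85	0.43
trnR-ACG-trnN-GUU	569	2	0	0.35	0.00
ycf1Truncated	1059	1	0	0.09	0.00
ndhF-rpl32	435	5	2	1.15	0.46
rpl32-trnL-UAG	737	13	2	1.76	0.27
ccsA-ndhD	180	4	0	2.22	0.00
ndhD-psaC	105	1	0	0.95	0.00
psaC-ndhE	251	5	0	1.99	0.00
ndhG-ndhI	375	6	0	1.60	0.00
rps15-ycf1 SSC	389	3	0	0.77	0.00
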
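region	length	pics_outgroup	pics_ingroup	pct_outgroup	pct_ingroup
trnK-UUU-1	264	5	0	1.89	0.00
trnk-UUU-2	714	5	0	0.70	0.00
rps16	874	5	1	0.57	0.11
trnG-UCC	689	7	0	1.02	0.00
atpF	655	3	0	0.46	0.00
rpoC1	762	4	1	0.52	0.13
ycf3-1	724	0	1	0.00	0.14
ycf3-2	712	2	0	0.28	0.00
trnL-UAA	487	4	0	0.82	0.00
trnV-UAC	478	1	1	0.21	0.21
clpP-1	615	6	0	0.98	0.00
clpP-2	657	4	0	0.61	0.00
petB	717	2	0	0.28	0.00
petD	727	4	2	0.55	0.28
rpl16	906	6	0	0.66	0.00
rpl2	657	2	2	0.30	0.30
trnI-GAU	937	1	0	0.11	0.00
ndhA	1019	10	7	0.98	0.69
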
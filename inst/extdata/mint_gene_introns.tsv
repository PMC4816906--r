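gene	location	n_introns	exon1	intron1	exon2	intron2	exon3
atpF	LSC	1	143	656	410		
clpP	LSC	2	70	658	291	616	227
ndhA	SSC	1	552	1020	538		
ndhB	IR	1	755	680	776		
petB	LSC	1	5	718	650		
petD	LSC	1	7	728	474		
rpl16	LSC	1	8	907	392		
rpl2	IR	1	390	658	433		
rpoC1	LSC	1	434	736	1634		
rps12	LSC/IR	2	113		231	537	25
rps16	LSC	1	39	875	226		
trnA-UGC	IR	1	37	807	34		
trnG-UCC	LSC	1	22	690	47		
trnI-GAU	IR	1	34	938	36		
trnK-UUU	LSC	1	36	2509	34		
trnL-UAA	LSC	1	36	488	49		
trnV-UAC	LSC	1	37	579	36		
ycf3	LSC	2	123	713	229	725	152
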
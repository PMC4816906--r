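species	lsc	ir	ssc	total
Haplostachys haplostachya	81755	25441	17495	150132
Haplostachys linearifolia	81752	25441	17495	150129
Phyllostegia velutina	81765	25440	17496	150141
Phyllostegia waimeae	81744	25448	17497	150137
Stachys byzantina	81245	25480	17517	149722
Stachys chamissonis	81774	25464	17552	150254
Stachys coccinea	82171	25470	17563	150674
Stachys sylvatica	81807	25414	17560	150195
Stenogyne bifida	81752	25441	17495	150129
Stenogyne haliakalae	81364	25436	17499	149736
Stenogyne kanehoana	81739	25441	17495	150116
Stenogyne sessilis	81743	25441	17495	150120
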
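begin	end	pics_outgroup	pics_ingroup
1	999	8	1
1000	1999	7	2
2000	2999	6	4
3000	3999	11	1
4000	4999	7	0
5000	5999	5	1
6000	6999	10	1
7000	7999	8	0
8000	8999	6	2
9000	9999	9	0
10000	10999	4	1
11000	11999	3	0
12000	12999	4	0
13000	13999	9	4
14000	14999	4	2
15000	15999	1	0
16000	16999	3	0
17000	17999	6	0
18000	18999	5	3
19000	19999	2	0
20000	20999	3	0
21000	21999	0	0
22000	22999	5	1
23000	23999	1	0
24000	24999	0	0
25000	25999	1	0
26000	26999	4	1
27000	27999	5	3
28000	28999	9	2
29000	29999	4	1
30000	30999	11	1
31000	31999	5	1
32000	32999	3	0
33000	33999	3	1
34000	34999	8	1
35000	35999	1	0
36000	36999	1	0
37000	37999	5	0
38000	38999	0	0
39000	39999	1	0
40000	40999	5	0
41000	41999	3	1
42000	42999	1	0
43000	43999	5	2
44000	44999	6	1
45000	45999	10	0
46000	46999	3	1
47000	47999	7	0
48000	48999	0	0
49000	49999	6	1
50000	50999	4	0
51000	51999	2	0
52000	52999	3	1
53000	53999	5	3
54000	54999	8	3
55000	55999	8	2
56000	56999	2	0
57000	57999	6	1
58000	58999	9	1
59000	59999	4	2
60000	60999	3	3
61000	61999	7	1
62000	62999	2	0
63000	63999	6	1
64000	64999	5	1
65000	65999	6	1
66000	66999	8	0
67000	67999	12	0
68000	68999	6	0
69000	69999	0	0
70000	70999	7	0
71000	71999	5	3
72000	72999	3	0
73000	73999	3	1
74000	74999	4	2
75000	75999	2	1
76000	76999	5	0
77000	77999	5	0
78000	78999	7	0
79000	79999	7	1
80000	80999	4	1
81000	81999	10	0
82000	82999	2	2
83000	83999	0	1
84000	84999	1	0
85000	85999	1	0
86000	86999	2	0
87000	87999	0	0
88000	88999	1	1
89000	89999	0	0
90000	90999	1	0
91000	91999	0	0
92000	92999	1	0
93000	93999	0	0
94000	94999	2	1
95000	95999	1	0
96000	96999	2	0
97000	97999	0	0
98000	98999	0	0
99000	99999	1	0
100000	100999	1	0
101000	101999	1	0
102000	102999	1	0
103000	103999	0	0
104000	104999	5	2
105000	105999	1	0
106000	106999	4	0
107000	107999	9	0
108000	108999	4	0
109000	109999	16	3
110000	110999	6	2
111000	111999	10	1
112000	112999	7	0
113000	113999	8	3
114000	114999	4	0
115000	115999	5	0
116000	116999	6	4
117000	117999	9	4
118000	118999	3	0
119000	119999	5	0
120000	120999	11	2
121000	121999	10	1
122000	122999	7	5
123000	123999	11	2
124000	124999	4	1
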
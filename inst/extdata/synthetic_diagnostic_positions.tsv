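position	sapiens	neanderthal	denisovan
459	C	A	G
678	A	C	G
1875	C	A	G
2384	G	A	C
2840	T	A	C
3252	G	A	C
3799	C	A	G
4705	T	A	C
5281	T	A	C
7498	A	C	G
9877	A	C	G
10281	T	A	C
10369	C	A	G
10426	G	A	C
10951	T	A	C
11098	C	A	G
11180	A	C	G
11757	G	A	C
12011	T	A	C
13480	A	C	G
13789	A	C	G
13820	G	A	C
14071	A	C	G
15451	A	C	G
16161	T	A	C
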
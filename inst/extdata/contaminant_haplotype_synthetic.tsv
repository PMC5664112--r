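notation	position	insertion_index	ref	alt	kind
769A	769	0	G	A	substitution
1018T	1018	0	A	T	substitution
1048G	1048	0	A	G	substitution
2758T	2758	0	A	T	substitution
2885C	2885	0	T	C	substitution
3107C	3107	0	N	C	substitution
3594A	3594	0	G	A	substitution
4104A	4104	0	T	A	substitution
4312A	4312	0	T	A	substitution
7146T	7146	0	A	T	substitution
7256C	7256	0	T	C	substitution
8468G	8468	0	A	G	substitution
8701C	8701	0	A	C	substitution
9042A	9042	0	T	A	substitution
9347G	9347	0	A	G	substitution
9540G	9540	0	A	G	substitution
10398G	10398	0	A	G	substitution
10873C	10873	0	A	C	substitution
12007C	12007	0	T	C	substitution
12705C	12705	0	G	C	substitution
13650A	13650	0	C	A	substitution
15301A	15301	0	T	A	substitution
16188G	16188	0	C	G	substitution
16223G	16223	0	T	G	substitution
16278C	16278	0	T	C	substitution
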
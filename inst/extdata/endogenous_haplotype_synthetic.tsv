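notation	position	insertion_index	ref	alt	kind
285A	285	0	C	A	substitution
309.1C	309	1		C	insertion
309.2C	309	2		C	insertion
385G	385	0	T	G	substitution
627T	627	0	A	T	substitution
980C	980	0	G	C	substitution
1290G	1290	0	C	G	substitution
1709C	1709	0	T	C	substitution
2218T	2218	0	A	T	substitution
3107C	3107	0	N	C	substitution
3158.1T	3158	1		T	insertion
4811G	4811	0	T	G	substitution
5198T	5198	0	A	T	substitution
5480G	5480	0	A	G	substitution
6026A	6026	0	T	A	substitution
6371T	6371	0	C	T	substitution
7581C	7581	0	A	C	substitution
8155G	8155	0	A	G	substitution
8573A	8573	0	G	A	substitution
8901A	8901	0	C	A	substitution
9667T	9667	0	C	T	substitution
10750A	10750	0	C	A	substitution
11065G	11065	0	T	G	substitution
12308A	12308	0	T	A	substitution
12358G	12358	0	C	G	substitution
12372A	12372	0	C	A	substitution
13104T	13104	0	A	T	substitution
13422A	13422	0	C	A	substitution
13734G	13734	0	C	G	substitution
14070C	14070	0	T	C	substitution
14364A	14364	0	C	A	substitution
15148G	15148	0	T	G	substitution
15954C	15954	0	T	C	substitution
16093T	16093	0	C	T	substitution
16129A	16129	0	G	A	substitution
16189A	16189	0	T	A	substitution
16249T	16249	0	A	T	substitution
16327C	16327	0	T	C	substitution
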
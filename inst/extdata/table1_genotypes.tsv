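individual_id	subpop	DRB*01	DRB*02	DRB*03	DRB*04	DRB*05	DRB*06	DRB*07	DRB*08	DRB*09	DRB*10	DRB*11	DRB*PS01	DRB*PS02	DRB*PS03	total_functional	total_pseudogene
1	east	0	1	1	0	0	1	0	1	1	0	0	1	0	0	5	1
2	east	1	1	1	0	0	0	1	0	0	0	0	1	0	0	4	1
3	east	1	1	1	0	0	0	0	0	0	0	0	1	0	0	3	1
4	east	1	1	1	0	0	0	0	0	0	0	0	1	0	1	3	2
5	east	1	1	1	1	0	0	0	0	0	0	0	1	0	0	4	1
6	east	1	1	1	1	0	0	0	0	0	0	0	1	1	0	4	2
7	east	1	1	1	0	0	0	0	0	0	0	0	1	0	0	3	1
8	east	1	1	1	0	0	0	0	0	0	0	0	1	0	0	3	1
9	east	1	1	1	0	0	0	0	0	0	0	0	1	0	0	3	1
10	east	1	1	1	0	0	0	0	0	0	0	0	1	0	0	3	1
11	east	1	1	1	0	0	0	0	0	0	1	0	1	0	1	4	2
12	east	0	1	1	0	0	0	0	0	0	0	0	1	0	0	2	1
21	east	0	1	1	0	0	0	0	0	0	0	0	1	0	0	2	1
22	east	1	1	1	0	0	0	0	0	0	0	0	1	0	0	3	1
23	east	0	1	1	0	0	0	0	0	0	0	0	1	0	0	2	1
24	east	1	1	1	0	0	0	0	0	0	0	0	1	0	0	3	1
29	east	1	1	1	0	0	0	0	0	0	0	0	1	0	0	3	1
30	east	0	1	1	0	0	0	0	0	0	0	0	1	0	0	2	1
32	east	0	1	1	0	0	0	0	0	0	0	0	1	0	0	2	1
13	north	1	0	0	0	0	0	0	0	0	0	0	1	0	0	1	1
14	north	1	0	0	0	0	0	0	0	0	0	0	1	0	0	1	1
15	north	1	0	0	1	0	0	0	0	0	0	0	1	0	0	2	1
16	admixed	1	0	0	0	0	0	0	0	0	0	0	1	0	0	1	1
17	north	1	1	1	0	0	1	0	0	0	0	1	1	0	0	5	1
18	north	1	1	1	0	0	0	0	0	0	0	0	1	0	0	3	1
19	north	1	0	0	0	0	0	0	0	0	0	0	1	0	0	1	1
20	north	1	1	1	0	0	0	0	0	0	0	0	1	0	0	3	1
25	north	1	0	0	0	0	0	0	0	0	0	0	1	0	0	1	1
26	admixed	1	0	0	0	0	0	0	0	0	0	0	1	0	0	1	1
27	north	1	0	0	0	1	0	0	0	0	0	0	1	0	0	2	1
28	north	1	0	0	0	1	0	0	0	0	0	0	1	0	0	2	1
31	north	1	1	1	0	0	0	0	0	0	0	0	1	0	0	3	1
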
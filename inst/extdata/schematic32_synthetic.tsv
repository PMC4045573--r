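# Synthetic 32-node schematic: three communities (1-11, 13-22, 23-32),
# node 12 overlaps the first two (4 edges into each), hubs 16 and 24
# each carry a single bridging edge. Columns: u v (conductance 1).
1	2
1	7
1	9
1	10
1	11
1	12
2	3
2	4
2	5
2	9
2	10
2	11
3	10
3	11
3	24
4	5
4	6
4	9
4	10
4	11
5	10
5	11
5	12
6	7
6	10
6	12
7	8
7	10
8	10
8	11
9	10
9	11
10	11
11	12
12	15
12	16
12	17
12	18
13	14
13	15
13	16
13	17
13	18
13	19
13	20
13	22
14	15
14	16
14	21
15	16
15	17
15	20
15	21
15	22
16	17
16	18
16	19
16	20
16	21
16	22
16	23
17	18
17	21
18	19
18	22
19	22
21	22
23	24
23	27
24	25
24	26
24	27
24	28
24	29
24	30
24	31
24	32
25	26
25	28
25	31
25	32
26	29
27	28
27	29
28	29
28	32
29	31
29	32
30	31
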
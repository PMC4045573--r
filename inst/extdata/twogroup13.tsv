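# Two mirrored 6-node groups joined by the central connector 7 and a direct
# gateway-gateway edge (6-8); the connector lies on no shortest path.
# Columns: u v (conductance defaults to 1).
1	2
1	4
1	5
2	3
2	5
3	5
3	6
4	5
4	6
5	6
6	7
6	8
7	8
8	9
8	12
8	13
9	11
9	13
10	11
10	12
10	13
11	13
12	13
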
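# name: S1
# laterality: right
# provenance: synthetic reconstruction of the 24-sector concentric RP map; emulates the documented structure (24 sectors, concentric rings, horizontal-crossing sectors include 6,9,11,12,14,15,16); not a figure transcription
point_index,x_deg,y_deg,sector_id
0,-1,9,1
1,1,9,2
2,-5,7,1
3,-3,7,3
4,-1,7,3
5,1,7,4
6,3,7,4
7,5,7,2
8,-7,5,1
9,-5,5,3
10,-3,5,5
11,-1,5,5
12,1,5,17
13,3,5,17
14,5,5,4
15,7,5,2
16,-7,3,7
17,-5,3,8
18,-3,3,13
19,-1,3,13
20,1,3,13
21,3,3,13
22,5,3,14
23,7,3,15
24,-9,1,6
25,-7,1,7
26,-5,1,8
27,-3,1,9
28,-1,1,10
29,1,1,11
30,3,1,12
31,5,1,14
32,7,1,15
33,9,1,16
34,-9,-1,6
35,-7,-1,7
36,-5,-1,8
37,-3,-1,9
38,-1,-1,10
39,1,-1,11
40,3,-1,12
41,5,-1,14
42,7,-1,15
43,9,-1,16
44,-7,-3,7
45,-5,-3,8
46,-3,-3,18
47,-1,-3,18
48,1,-3,18
49,3,-3,18
50,5,-3,14
51,7,-3,15
52,-7,-5,23
53,-5,-5,21
54,-3,-5,19
55,-1,-5,19
56,1,-5,20
57,3,-5,20
58,5,-5,22
59,7,-5,24
60,-5,-7,23
61,-3,-7,21
62,-1,-7,21
63,1,-7,22
64,3,-7,22
65,5,-7,24
66,-1,-9,23
67,1,-9,24
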
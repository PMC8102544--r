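# name: S2
# laterality: right
# provenance: synthetic reconstruction of the 29-sector glaucoma map; emulates the documented structure (29 sectors, no sector crosses the horizontal midline); not a figure transcription
point_index,x_deg,y_deg,sector_id
0,-1,9,1
1,1,9,1
2,-5,7,2
3,-3,7,2
4,-1,7,1
5,1,7,1
6,3,7,3
7,5,7,3
8,-7,5,4
9,-5,5,4
10,-3,5,5
11,-1,5,5
12,1,5,5
13,3,5,5
14,5,5,6
15,7,5,6
16,-7,3,7
17,-5,3,7
18,-3,3,8
19,-1,3,8
20,1,3,9
21,3,3,9
22,5,3,10
23,7,3,10
24,-9,1,11
25,-7,1,11
26,-5,1,12
27,-3,1,12
28,-1,1,13
29,1,1,13
30,3,1,14
31,5,1,14
32,7,1,15
33,9,1,15
34,-9,-1,16
35,-7,-1,16
36,-5,-1,17
37,-3,-1,17
38,-1,-1,18
39,1,-1,18
40,3,-1,19
41,5,-1,19
42,7,-1,20
43,9,-1,20
44,-7,-3,21
45,-5,-3,21
46,-3,-3,22
47,-1,-3,22
48,1,-3,22
49,3,-3,22
50,5,-3,23
51,7,-3,23
52,-7,-5,24
53,-5,-5,24
54,-3,-5,25
55,-1,-5,25
56,1,-5,25
57,3,-5,25
58,5,-5,26
59,7,-5,26
60,-5,-7,27
61,-3,-7,27
62,-1,-7,28
63,1,-7,28
64,3,-7,29
65,5,-7,29
66,-1,-9,28
67,1,-9,28
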
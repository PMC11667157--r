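channel,name,row,col
1,FC5,4,3
2,FC3,4,4
3,FC1,4,5
4,FCz,4,6
5,FC2,4,7
6,FC4,4,8
7,FC6,4,9
8,C5,5,3
9,C3,5,4
10,C1,5,5
11,Cz,5,6
12,C2,5,7
13,C4,5,8
14,C6,5,9
15,CP5,6,3
16,CP3,6,4
17,CP1,6,5
18,CPz,6,6
19,CP2,6,7
20,CP4,6,8
21,CP6,6,9
22,Fp1,1,5
23,Fpz,1,6
24,Fp2,1,7
25,AF7,2,4
26,AF3,2,5
27,AFz,2,6
28,AF4,2,7
29,AF8,2,8
30,F7,3,2
31,F5,3,3
32,F3,3,4
33,F1,3,5
34,Fz,3,6
35,F2,3,7
36,F4,3,8
37,F6,3,9
38,F8,3,10
39,FT7,4,2
40,FT8,4,10
41,T7,5,2
42,T8,5,10
43,T9,5,1
44,T10,5,11
45,TP7,6,2
46,TP8,6,10
47,P7,7,2
48,P5,7,3
49,P3,7,4
50,P1,7,5
51,Pz,7,6
52,P2,7,7
53,P4,7,8
54,P6,7,9
55,P8,7,10
56,PO7,8,4
57,PO3,8,5
58,POz,8,6
59,PO4,8,7
60,PO8,8,8
61,O1,9,5
62,Oz,9,6
63,O2,9,7
64,Iz,10,6
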
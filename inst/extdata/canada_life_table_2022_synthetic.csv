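age,q_annual
0,0.00437
1,0.00029
2,0.00021
3,0.00016
4,0.00013
5,0.00012
6,0.00011
7,0.00010
8,0.00010
9,0.00010
10,0.00011
11,0.00012
12,0.00014
13,0.00018
14,0.00023
15,0.00030
16,0.00038
17,0.00046
18,0.00055
19,0.00063
20,0.00070
21,0.00076
22,0.00080
23,0.00083
24,0.00085
25,0.00087
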
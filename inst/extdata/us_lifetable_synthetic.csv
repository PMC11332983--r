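# Synthetic stand-in for a US all-population period life table.
# Gompertz-Makeham: qx = 0.0004 + A*exp(0.0852*age), A chosen so q(60) = 0.00902;
# calibrated a priori to published all-population anchors (q40~0.0020, q80~0.050).
# Not an official vital-statistics product; swap in a real table via read_life_table().
age,qx
30,0.001069
31,0.001129
32,0.001193
33,0.001264
34,0.001341
35,0.001424
36,0.001515
37,0.001615
38,0.001723
39,0.001840
40,0.001968
41,0.002108
42,0.002260
43,0.002425
44,0.002605
45,0.002801
46,0.003015
47,0.003248
48,0.003501
49,0.003777
50,0.004077
51,0.004404
52,0.004760
53,0.005148
54,0.005570
55,0.006030
56,0.006531
57,0.007076
58,0.007669
59,0.008316
60,0.009020
61,0.009787
62,0.010621
63,0.011530
64,0.012520
65,0.013598
66,0.014772
67,0.016050
68,0.017442
69,0.018958
70,0.020608
71,0.022405
72,0.024362
73,0.026493
74,0.028814
75,0.031341
76,0.034093
77,0.037089
78,0.040352
79,0.043905
80,0.047775
81,0.051988
82,0.056576
83,0.061572
84,0.067012
85,0.072936
86,0.079387
87,0.086412
88,0.094061
89,0.102391
90,0.111462
91,0.121339
92,0.132095
93,0.143807
94,0.156561
95,0.170449
96,0.185572
97,0.202040
98,0.219973
99,0.239501
100,0.260765
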
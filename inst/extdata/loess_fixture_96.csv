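"x","y"
1,112.059
2,129.858
3,120.497
4,115.616
5,118.089
6,116.967
7,145.854
8,126.414
9,146.113
10,131.449
11,148.438
12,153.992
13,152.553
14,138.961
15,160.642
16,164.817
17,143.038
18,161.388
19,185.171
20,166.22
21,178.549
22,156.054
23,147.432
24,170.289
25,148.207
26,137.925
27,129.813
28,139.947
29,119.175
30,125.417
31,112.519
32,101.145
33,127.495
34,105.454
35,98.772
36,121.013
37,94.934
38,96.599
39,96.491
40,94.008
41,100.041
42,97.027
43,109.787
44,97.555
45,100.63
46,99.258
47,102.426
48,108.986
49,108.274
50,94.847
51,100.269
52,109.695
53,133.102
54,116.343
55,118.635
56,126.778
57,137.579
58,133.716
59,137.391
60,146.015
61,127.733
62,148.902
63,155.315
64,125.045
65,146.837
66,158.364
67,158.668
68,158.223
69,160.87
70,174.736
71,160.326
72,153.709
73,157.119
74,152.072
75,154.4
76,144.761
77,160.366
78,158.581
79,149.13
80,157.187
81,141.902
82,135.056
83,136.273
84,134.887
85,145.297
86,126.978
87,103.645
88,101.441
89,123.867
90,114.679
91,99.691
92,111.047
93,105.911
94,105.603
95,109.011
96,120.551
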
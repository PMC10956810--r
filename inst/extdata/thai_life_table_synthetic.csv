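age,annual_mortality
0,6.569503244169645e-5
1,7.164094087536494e-5
2,7.8125e-5
3,8.519591661447326e-5
4,9.290680585958758e-5
5,1.0131559020711013e-4
6,1.1048543456039807e-4
7,1.2048522073499537e-4
8,1.313900648833929e-4
9,1.4328188175072987e-4
10,1.5625e-4
11,1.7039183322894652e-4
12,1.8581361171917516e-4
13,2.0263118041422026e-4
14,2.2097086912079613e-4
15,2.4097044146999074e-4
16,2.627801297667858e-4
17,2.8656376350145974e-4
18,3.125e-4
19,3.4078366645789304e-4
20,3.716272234383503e-4
21,4.052623608284405e-4
22,4.4194173824159226e-4
23,4.819408829399815e-4
24,5.255602595335716e-4
25,5.731275270029195e-4
26,6.25e-4
27,6.815673329157861e-4
28,7.432544468767006e-4
29,8.10524721656881e-4
30,8.838834764831845e-4
31,9.63881765879963e-4
32,0.0010511205190671432
33,0.001146255054005839
34,0.00125
35,0.0013631346658315722
36,0.0014865088937534012
37,0.001621049443313762
38,0.001767766952966369
39,0.001927763531759926
40,0.0021022410381342864
41,0.002292510108011678
42,0.0025
43,0.0027262693316631443
44,0.0029730177875068025
45,0.003242098886627524
46,0.003535533905932738
47,0.003855527063519852
48,0.004204482076268573
49,0.004585020216023356
50,0.005
51,0.005452538663326289
52,0.005946035575013605
53,0.006484197773255048
54,0.007071067811865476
55,0.007711054127039704
56,0.008408964152537146
57,0.009170040432046712
58,0.01
59,0.010905077326652577
60,0.01189207115002721
61,0.012968395546510096
62,0.014142135623730952
63,0.015422108254079407
64,0.01681792830507429
65,0.018340080864093423
66,0.02
67,0.021810154653305155
68,0.02378414230005442
69,0.025936791093020193
70,0.028284271247461905
71,0.030844216508158814
72,0.03363585661014858
73,0.03668016172818685
74,0.04
75,0.04362030930661031
76,0.04756828460010884
77,0.051873582186040386
78,0.05656854249492381
79,0.06168843301631763
80,0.06727171322029717
81,0.0733603234563737
82,0.08
83,0.08724061861322062
84,0.09513656920021768
85,0.10374716437208077
86,0.11313708498984762
87,0.12337686603263526
88,0.13454342644059433
89,0.1467206469127474
90,0.16
91,0.17448123722644124
92,0.19027313840043536
93,0.20749432874416154
94,0.22627416997969524
95,0.24675373206527051
96,0.26908685288118867
97,0.2934412938254948
98,0.32
99,0.3489624744528825
100,0.3805462768008707
101,0.4149886574883231
102,0.4525483399593905
103,0.49350746413054103
104,0.5381737057623773
105,0.5868825876509896
106,0.64
107,0.697924948905765
108,0.7610925536017414
109,0.8299773149766462
110,0.905096679918781
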
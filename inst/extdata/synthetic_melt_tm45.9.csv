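"temperature_C","cd_235nm"
25,1.00857
25.5,1.00712
26,0.99743
26.5,0.98927
27,0.99814
27.5,0.99699
28,1.00168
28.5,1.01056
29,0.98312
29.5,0.98154
30,0.98803
30.5,1.00333
31,1.00428
31.5,1.00889
32,1.01202
32.5,0.98824
33,0.98245
33.5,1.00537
34,0.99593
34.5,1.00071
35,0.98367
35.5,0.98057
36,0.97329
36.5,0.98646
37,0.96377
37.5,0.97027
38,0.98391
38.5,0.97362
39,0.95083
39.5,0.94273
40,0.91942
40.5,0.92481
41,0.91117
41.5,0.88182
42,0.8614
42.5,0.81519
43,0.78373
43.5,0.729
44,0.70638
44.5,0.66905
45,0.61998
45.5,0.55327
46,0.49488
46.5,0.46134
47,0.37383
47.5,0.33225
48,0.29186
48.5,0.22943
49,0.19034
49.5,0.14713
50,0.11071
50.5,0.11881
51,0.08916
51.5,0.04696
52,0.05531
52.5,0.0532
53,0.04095
53.5,0.01043
54,0.0343
54.5,0.01171
55,0.01386
55.5,0.00455
56,0.00466
56.5,-0.0059
57,0.01413
57.5,0.02891
58,0.01079
58.5,-0.00341
59,0.0065
59.5,-0.00637
60,0.00071
60.5,0.01508
61,0.01329
61.5,-0.00543
62,0.02309
62.5,-0.01094
63,0.00655
63.5,-0.00758
64,-0.00577
64.5,-0.00269
65,0.00211
65.5,-0.00233
66,-0.00229
66.5,8e-05
67,0.00365
67.5,0.00134
68,-0.00506
68.5,-0.01463
69,0.0147
69.5,-0.01352
70,-0.00051
70.5,-0.00683
71,-0.01258
71.5,-0.00579
72,-0.00112
72.5,0.01135
73,-0.01193
73.5,0.01157
74,0.01216
74.5,0.00771
75,0.00425
75.5,-0.00892
76,0.00586
76.5,-0.00051
77,-0.00113
77.5,0.00736
78,0.00694
78.5,0.00014
79,0.00807
79.5,-0.00417
80,0.00245
80.5,-0.00015
81,-0.01611
81.5,0.00146
82,0.00885
82.5,-0.01458
83,0.01206
83.5,-0.01312
84,-0.00196
84.5,0.01252
85,-0.00448
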
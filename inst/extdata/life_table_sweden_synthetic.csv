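age,sex,qx
40,male,0.00132271696098454
41,male,0.00141243078471
42,male,0.00151192752351941
43,male,0.00162227396314953
44,male,0.00174465321783413
45,male,0.00188037741543724
46,male,0.00203090176584682
47,male,0.00219784016346757
48,male,0.00238298249109997
49,male,0.00258831381073449
50,male,0.00281603564702126
51,male,0.00306858959161247
52,male,0.00334868348145911
53,male,0.00365932043174079
54,male,0.00400383103471443
55,male,0.00438590906971201
56,male,0.00480965110716327
57,male,0.00527960043127053
58,male,0.00580079575226645
59,male,0.00637882523053852
60,male,0.00701988639185717
61,male,0.00773085257610734
62,male,0.00851934663197482
63,male,0.00939382264772799
64,male,0.0103636565943977
65,male,0.0114392468532144
66,male,0.0126321257051395
67,male,0.0139550829778611
68,male,0.0154223031759748
69,male,0.0170495175646331
70,male,0.0188541728372776
71,male,0.0208556181758781
72,male,0.0230753127093031
73,male,0.0255370555941536
74,male,0.0282672411849434
75,male,0.0312951420295147
76,male,0.0346532227239131
77,male,0.0383774879918161
78,male,0.0425078687205595
79,male,0.0470886500927685
80,male,0.052168946403942
81,male,0.057803227656897
82,male,0.0640519035791225
83,male,0.0709819713247681
84,male,0.0786677338058114
85,male,0.0871915963542156
86,male,0.0966449502567453
87,male,0.107129152635537
88,male,0.118756613180524
89,male,0.13165199938546
90,male,0.145953573209863
91,male,0.161814673498316
92,male,0.179405360051367
93,male,0.198914236975431
94,male,0.220550474861342
95,male,0.244546053472957
96,male,0.271158248991529
97,male,0.300672392483611
98,male,0.333404929168276
99,male,0.369706811284572
100,male,1
40,female,0.000794124609650106
41,female,0.000849928204060828
42,female,0.000912033935803592
43,female,0.000981153532059618
44,female,0.00105807909838873
45,female,0.00114369219620162
46,female,0.00123897394538968
47,female,0.00134501626788777
48,female,0.00146303440102044
49,female,0.0015943808240335
50,female,0.00174056075740805
51,female,0.0019032494125781
52,female,0.00208431118973203
53,female,0.00228582104370353
54,female,0.00251008826280355
55,female,0.00275968293309678
56,female,0.00303746539140158
57,female,0.00334661900454247
58,female,0.00369068665050302
59,female,0.00407361131955058
60,female,0.00449978130061877
61,female,0.00497408047078037
62,female,0.00550194426412432
63,female,0.00608942196143621
64,female,0.00674324601451724
65,female,0.00747090919959363
66,female,0.00828075048398868
67,female,0.00918205059008345
68,female,0.0101851383517222
69,female,0.0113015090818989
70,female,0.0125439563082107
71,female,0.0139267183857559
72,female,0.015465641667651
73,female,0.0171783621030877
74,female,0.0190845073440321
75,female,0.0212059216766917
76,female,0.0235669163554521
77,female,0.0261945482080879
78,female,0.0291189297050473
79,female,0.0323735740461788
80,female,0.0359957792195715
81,female,0.0400270554337924
82,female,0.0445136008218666
83,female,0.0495068308685306
84,female,0.0550639676279584
85,female,0.0612486954843518
86,female,0.0681318909703645
87,female,0.0757924350070254
88,female,0.0843181168733729
89,female,0.093806640265224
90,female,0.104366742972444
91,female,0.116119443006128
92,female,0.129199425456236
93,female,0.143756585972949
94,female,0.159957748559954
95,female,0.17798857736542
96,female,0.198055704379675
97,female,0.220389097422828
98,female,0.245244695559303
99,female,0.272907342140958
100,female,1
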
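"aa","CDR2.1","CDR2.2","CDR2.3","CDR2.4"
"A",0.05,0.05,0.0476190476190476,0.05
"R",0,0,0,0
"N",0.1,0.1,0.114285714285714,0.1
"D",0.1,0.1,0.142857142857143,0.1
"C",0,0,0,0
"Q",0,0,0,0
"E",0,0,0,0
"G",0.15,0.2,0.142857142857143,0.15
"H",0,0,0,0
"I",0,0,0,0
"L",0.03,0.03,0.0285714285714286,0.03
"K",0,0,0,0
"M",0,0,0,0
"F",0,0,0,0
"P",0,0,0,0
"S",0.2,0.25,0.19047619047619,0.2
"T",0.1,0.1,0.0761904761904762,0.1
"W",0.05,0.05,0.0476190476190476,0.05
"Y",0.2,0.1,0.19047619047619,0.2
"V",0.02,0.02,0.019047619047619,0.02
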
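"aa","CDR3.1","CDR3.2","CDR3.3","CDR3.4","CDR3.5","CDR3.6","CDR3.7"
"A",0,0,0,0,0,0,0
"R",0.02,0.02,0.0188679245283019,0.02,0.0185185185185185,0.02,0.0181818181818182
"N",0.08,0.08,0.0754716981132075,0.08,0.0925925925925926,0.08,0.0727272727272727
"D",0.1,0.1,0.0943396226415094,0.1,0.12962962962963,0.1,0.0909090909090909
"C",0,0,0,0,0,0,0
"Q",0.05,0.05,0.0471698113207547,0.05,0.0462962962962963,0.05,0.0454545454545455
"E",0.05,0.05,0.0471698113207547,0.05,0.0648148148148148,0.05,0.0454545454545455
"G",0.2,0.15,0.141509433962264,0.15,0.138888888888889,0.15,0.163636363636364
"H",0.03,0.03,0.0283018867924528,0.03,0.0277777777777778,0.03,0.0272727272727273
"I",0,0,0,0,0,0,0
"L",0.02,0.02,0.0188679245283019,0.02,0.0185185185185185,0.02,0.0181818181818182
"K",0,0,0,0,0,0,0
"M",0,0,0,0,0,0,0
"F",0.01,0.01,0.0188679245283019,0.01,0.00925925925925926,0.01,0.00909090909090909
"P",0.04,0.04,0.0377358490566038,0.04,0.037037037037037,0.04,0.0545454545454545
"S",0.18,0.15,0.141509433962264,0.15,0.138888888888889,0.15,0.181818181818182
"T",0.08,0.08,0.0754716981132075,0.08,0.0740740740740741,0.08,0.0727272727272727
"W",0.04,0.04,0.0566037735849057,0.04,0.037037037037037,0.04,0.0363636363636364
"Y",0.07,0.15,0.169811320754717,0.15,0.138888888888889,0.15,0.136363636363636
"V",0.03,0.03,0.0283018867924528,0.03,0.0277777777777778,0.03,0.0272727272727273
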
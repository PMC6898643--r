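ablation,modality,tpr_pct,fdr_pct,adr
1,CECT,99,54,0.83
2,CECT,99,63,0.59
3,CECT,59,47,0.63
4,CECT,72,69,0.38
5,CECT,17,13,0.19
6,CECT,95,43,1.27
7,CECT,100,58,0.73
8,CECT,89,73,0.36
9,CECT,79,45,0.92
10,CECT,97,57,0.74
1,AF,100,57,0.76
2,AF,100,59,0.7
3,AF,76,33,1.23
4,AF,75,53,0.65
5,AF,59,6,1.34
6,AF,100,58,0.73
7,AF,100,58,0.73
8,AF,100,69,0.46
9,AF,94,54,0.8
10,AF,100,57,0.75
1,PF,100,59,0.71
2,PF,100,65,0.54
3,PF,100,48,1.07
4,PF,95,68,0.45
5,PF,100,80,0.25
6,PF,99,58,0.72
7,PF,100,58,0.73
8,PF,100,71,0.41
9,PF,80,67,0.44
10,PF,100,58,0.73
1,TF,100,53,0.89
2,TF,100,48,1.19
3,TF,100,39,1.57
4,TF,100,69,0.45
5,TF,100,80,0.25
6,TF,100,58,0.73
7,TF,100,58,0.73
8,TF,100,71,0.41
9,TF,100,70,0.42
10,TF,100,58,0.73
1,HBV,100,29,2.42
2,HBV,NA,NA,6.58
3,HBV,96,11,5.9
4,HBV,80,47,0.87
5,HBV,99,28,2.54
6,HBV,99,43,1.32
7,HBV,95,17,3.97
8,HBV,92,37,1.47
9,HBV,70,17,1.57
10,HBV,66,16,1.42
1,MTT,100,59,0.7
2,MTT,99,68,0.47
3,MTT,100,49,1.06
4,MTT,100,69,0.45
5,MTT,100,80,0.25
6,MTT,98,49,1.02
7,MTT,100,55,0.83
8,MTT,100,68,0.48
9,MTT,100,67,0.48
10,MTT,95,57,0.73
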
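agonist,background,EC50_uM,EC50_sem_uM,POmax,POmax_sem,KdC_uM,KdC_sem_uM,KdO_nM,KdO_sem_nM,c,c_sem,eta,eta_sem,n
BzTMA,eS450W,1070,200,0.60,0.05,930,112.0,650,90,1424,18.0,0.51,0.01,3
Dec,eL269F,190,20,0.79,0.03,90,7.0,140,10,643,21,0.41,0.01,4
SCh,eS450W,20,3,0.84,0.02,50,4.0,20,1,3177,118,0.45,0.01,3
BzTEA,eL269F+eE181W,2,0.1,0.85,0.02,0.80,0.3,3,2,316,14,0.29,0.00,3
TriMA,eL269F,16000,1200,0.78,0.03,7720,316.0,12580,670,615,18,0.57,0.01,4
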
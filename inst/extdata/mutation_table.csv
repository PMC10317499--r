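mutation,agonist,background,EC50_uM,EC50_sem_uM,POmax,POmax_sem,KdC_uM,KdC_sem_uM,KdO_nM,KdO_sem_nM,c,c_sem,eta,eta_sem,n,eta_wt
D200A,ACh,eS450W,110,10,0.80,0.02,52,3,150,5,338,12,0.37,0.00,3,0.50
D200A,CCh,eS450W,320,70,0.45,0.02,138,18,900,94,153,3,0.36,0.00,4,0.52
D200A,TMA,eS450W,13350,2970,0.37,0.03,5683,740,4382,890,130,5,0.48,0.02,5,0.54
D200A,Ebt,eS450W+eL269F,110,20,0.50,0.03,47,5,680,47,69,2,0.30,0.00,3,0.41
D200A,Ebx,eS450W+eL269F,60,20,0.49,0.03,26,5,390,58,67,3,0.29,0.01,3,0.46
K145A,ACh,eS450W,110,10,0.95,0.06,83,5,50,3,1672,82,0.44,0.00,3,NA
K145A,CCh,eS450W,380,30,0.53,0.01,165,8,400,15,411,5,0.41,0.00,4,NA
K145A,TMA,eS450W,2200,590,0.19,0.01,922,125,5010,712,184,3,0.43,0.01,3,NA
K145A,Ebt,eS450W,40,4,0.81,0.04,20,2,20,2,792,52,0.38,0.00,3,NA
K145A,Ebx,eS450W,40,3,0.83,0.01,20,1,20,1,847,17,0.38,0.00,3,NA
G153S,Ebt,eS450W,2,0.5,0.65,0.01,2,0.3,7,1,313,4,0.31,0.01,4,NA
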
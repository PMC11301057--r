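stratum,term,soc,a,b,c,d,N,E,ror,ror_low,ror_high,prr,chi2,ic,ic025,ebgm,eb05,flag_ror,flag_prr,flag_bcpnn,flag_mgps,retained
F,Nausea,Gastrointestinal disorders,2,1,1,4,8,1.125,8,0.3101,206.383,3.3333,1.7422,0.3959,-1.682,2,2,FALSE,FALSE,FALSE,FALSE,FALSE
F,Diarrhoea,Gastrointestinal disorders,1,2,0,5,8,0.375,,,,Inf,1.9048,0.2863,-2.4966,2,2,FALSE,FALSE,FALSE,FALSE,FALSE
M,Anaemia,Blood and lymphatic system disorders,1,2,1,1,5,1.2,0.5,0.0128,19.5637,0.6667,0.1389,-0.1535,-2.4101,1.2489,1.2489,FALSE,FALSE,FALSE,FALSE,FALSE
M,Nausea,Gastrointestinal disorders,1,2,0,2,5,0.6,,,,Inf,0.8333,0.139,-2.4135,1.2489,1.2489,FALSE,FALSE,FALSE,FALSE,FALSE
M,Mystery Syndrome,UNMAPPED,1,2,0,2,5,0.6,,,,Inf,0.8333,0.139,-2.4135,1.2489,1.2489,FALSE,FALSE,FALSE,FALSE,FALSE
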
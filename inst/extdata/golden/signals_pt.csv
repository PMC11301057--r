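term,soc,a,b,c,d,N,E,ror,ror_low,ror_high,prr,chi2,ic,ic025,ebgm,eb05,flag_ror,flag_prr,flag_bcpnn,flag_mgps,retained
Anaemia,Blood and lymphatic system disorders,2,6,1,6,15,1.6,2,0.1408,28.4173,1.75,0.2679,0.0647,-1.9914,1.5,1.4998,FALSE,FALSE,FALSE,FALSE,FALSE
Nausea,Gastrointestinal disorders,4,4,1,6,15,2.6667,6,0.4778,75.3473,3.5,2.1429,0.3949,-1.1724,1.5,1.4998,FALSE,FALSE,FALSE,FALSE,FALSE
Diarrhoea,Gastrointestinal disorders,1,7,0,7,15,0.5333,,,,Inf,0.9375,0.0482,-2.7182,1.5,1.4998,FALSE,FALSE,FALSE,FALSE,FALSE
Mystery Syndrome,UNMAPPED,1,7,0,7,15,0.5333,,,,Inf,0.9375,0.0482,-2.7182,1.5,1.4998,FALSE,FALSE,FALSE,FALSE,FALSE
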
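term,soc,a,b,c,d,N,E,ror,ror_low,ror_high,prr,chi2,ic,ic025,ebgm,eb05,flag_ror,flag_prr,flag_bcpnn,flag_mgps,retained
Blood and lymphatic system disorders,Blood and lymphatic system disorders,2,5,1,6,14,1.5,2.4,0.1649,34.9297,2,0.4242,0.1255,-1.9364,1.2728,1.2728,FALSE,FALSE,FALSE,FALSE,FALSE
Gastrointestinal disorders,Gastrointestinal disorders,4,3,3,4,14,3.5,1.7778,0.214,14.7672,1.3333,0.2857,0.152,-1.3036,1.2728,1.2728,FALSE,FALSE,FALSE,FALSE,FALSE
UNMAPPED,UNMAPPED,1,6,0,7,14,0.5,,,,Inf,1.0769,0.0931,-2.6778,1.2728,1.2728,FALSE,FALSE,FALSE,FALSE,FALSE
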
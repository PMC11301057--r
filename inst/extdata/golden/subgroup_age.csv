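stratum,term,soc,a,b,c,d,N,E,ror,ror_low,ror_high,prr,chi2,ic,ic025,ebgm,eb05,flag_ror,flag_prr,flag_bcpnn,flag_mgps,retained
18-<65,Anaemia,Blood and lymphatic system disorders,1,2,0,4,7,0.4286,,,,Inf,1.5556,0.2418,-2.4837,2.3335,2.3335,FALSE,FALSE,FALSE,TRUE,FALSE
18-<65,Nausea,Gastrointestinal disorders,1,2,0,4,7,0.4286,,,,Inf,1.5556,0.2418,-2.4837,2.3335,2.3335,FALSE,FALSE,FALSE,TRUE,FALSE
18-<65,Mystery Syndrome,UNMAPPED,1,2,0,4,7,0.4286,,,,Inf,1.5556,0.2418,-2.4837,2.3335,2.3335,FALSE,FALSE,FALSE,TRUE,FALSE
>=65,Anaemia,Blood and lymphatic system disorders,1,2,1,2,6,1,1,0.0335,29.8093,1,0,-0.0875,-2.4575,1.2,1.1999,FALSE,FALSE,FALSE,FALSE,FALSE
>=65,Nausea,Gastrointestinal disorders,2,1,1,2,6,1.5,4,0.1342,119.2371,2,0.6667,0.263,-1.6386,1.2,1.1999,FALSE,FALSE,FALSE,FALSE,FALSE
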
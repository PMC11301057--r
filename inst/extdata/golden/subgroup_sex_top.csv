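stratum,rank_in_stratum,term,soc,a,ror,retained
F,1,Nausea,Gastrointestinal disorders,2,8,FALSE
F,2,Diarrhoea,Gastrointestinal disorders,1,,FALSE
M,1,Anaemia,Blood and lymphatic system disorders,1,0.5,FALSE
M,2,Mystery Syndrome,UNMAPPED,1,,FALSE
M,3,Nausea,Gastrointestinal disorders,1,,FALSE
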
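stratum,rank_in_stratum,term,soc,a,ror,retained
18-<65,1,Anaemia,Blood and lymphatic system disorders,1,,FALSE
18-<65,2,Mystery Syndrome,UNMAPPED,1,,FALSE
18-<65,3,Nausea,Gastrointestinal disorders,1,,FALSE
>=65,1,Nausea,Gastrointestinal disorders,2,4,FALSE
>=65,2,Anaemia,Blood and lymphatic system disorders,1,1,FALSE
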
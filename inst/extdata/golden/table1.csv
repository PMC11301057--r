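section,level,n,pct
Sex,Female,2,40
Sex,Male,2,40
Sex,Missing,1,20
Age,<18,1,20
Age,18-<65,2,40
Age,>=65,2,40
Outcome,Death,1,20
Outcome,Hospitalization - Initial or Prolonged,2,40
Outcome,Missing,3,60
Indications (top 7),COLON CANCER,3,60
Indications (top 7),COLORECTAL CANCER METASTATIC,1,20
Indications (top 7),RECTAL CANCER,1,20
Reported person,Consumer,2,40
Reported person,Physician,2,40
Reported person,Health Professional,1,20
Reported countries (top 5),US,3,60
Reported countries (top 5),FR,1,20
Reported countries (top 5),JP,1,20
Year,2020,5,100
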
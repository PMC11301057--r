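bin,n,pct
0-30,0,0
31-60,2,100
61-90,0,0
91-180,0,0
181-365,0,0
>365,0,0
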
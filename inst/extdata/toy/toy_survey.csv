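site,transect,species_code,count
S1,T1,LC,5
S1,T1,AAA,3
S1,T1,BBB,2
S1,T2,LC,4
S1,T2,AAA,2
S1,T2,BBB,3
S1,T3,PJ,6
S1,T3,CCC,2
S1,T3,DDD,1
S2,T1,LC,4
S2,T1,EEE,2
S2,T2,PJ,3
S2,T2,FFF,2
S2,T3,PJ,3
S2,T3,FFF,2
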
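site,clique_rank,species_code,is_hub,status,dominant_invasive
S1,1,AAA,TRUE,native,LC
S1,1,BBB,TRUE,native,LC
S1,1,LC,TRUE,invasive,LC
S1,2,CCC,TRUE,native,PJ
S1,2,DDD,TRUE,native,PJ
S1,2,PJ,TRUE,invasive,PJ
S2,1,EEE,TRUE,native,LC
S2,1,LC,TRUE,invasive,LC
S2,2,FFF,TRUE,native,PJ
S2,2,PJ,TRUE,invasive,PJ
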
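code,scientific_name,status
LC,Lantana toyensis,invasive
PJ,Prosopis toyensis,invasive
AAA,Toyplant alpha,native
BBB,Toyplant beta,native
CCC,Toyplant gamma,native
DDD,Toyplant delta,native
EEE,Toyplant epsilon,native
FFF,Toyplant zeta,native
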
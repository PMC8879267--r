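site,clique_rank,species_code,species_name,status,is_hub
SV,1,LL,Leucaena leucocephala,invasive,TRUE
SV,1,CF,Cassia fistula,native,FALSE
SV,1,PP,Pongamia pinnata,native,FALSE
SV,1,AE,Ailanthus excelsa,native,FALSE
SV,1,CAR,Carissa spinarum,native,FALSE
SV,2,AI,Azadirachta indica,introduced,TRUE
SV,2,LC,Lantana camara,invasive,FALSE
SV,2,GRE,Grewia tenax,native,FALSE
SV,2,HI,Holoptelea integrifolia,native,FALSE
SV,2,DS,Dalbergia sissoo,native,FALSE
SV,3,ADV,Adhatoda vasica,native,TRUE
SV,3,CS,Capparis sepiaria,native,FALSE
SV,3,BR,Balanites roxburghii,native,FALSE
SV,4,CD,Capparis decidua,native,TRUE
SV,4,PJ,Prosopis juliflora,invasive,FALSE
SV,4,DC,Diospyros cordifolia,native,FALSE
SV,4,MS,Maytenus senegalensis,native,FALSE
SV,5,TG,Tectona grandis,native,TRUE
SV,5,AS,Acacia senegal,native,FALSE
SV,5,ZM,Ziziphus mauritiana,native,FALSE
SV,5,PC,Prosopis cineraria,native,FALSE
TUQ,1,BR,Balanites roxburghii,native,TRUE
TUQ,1,PJ,Prosopis juliflora,invasive,FALSE
TUQ,1,CS,Capparis sepiaria,native,FALSE
TUQ,2,AN,Acacia nilotica,native,TRUE
TUQ,2,CF,Cassia fistula,native,FALSE
TUQ,2,AL,Acacia leucophloea,native,FALSE
TUQ,2,PC,Prosopis cineraria,native,FALSE
TUQ,3,GRE,Grewia tenax,native,TRUE
TUQ,3,HI,Holoptelea integrifolia,native,FALSE
TUQ,3,PP,Pongamia pinnata,native,FALSE
TUQ,3,ZN,Ziziphus nummularia,native,FALSE
TUQ,3,DC,Diospyros cordifolia,native,FALSE
TUQ,4,AI,Azadirachta indica,introduced,TRUE
TUQ,4,CD,Capparis decidua,native,FALSE
TUQ,4,ADV,Adhatoda vasica,native,FALSE
TUQ,5,LC,Lantana camara,invasive,TRUE
TUQ,5,BS,Bougainvillea spectabilis,native,FALSE
HK,1,SS,Senna siamea,native,TRUE
HK,1,PP,Pongamia pinnata,native,FALSE
HK,1,CS,Capparis sepiaria,native,FALSE
HK,1,EL,Ehretia laevis,native,FALSE
HK,2,LL,Leucaena leucocephala,invasive,TRUE
HK,2,MOA,Morus alba,introduced,FALSE
HK,2,ADV,Adhatoda vasica,native,FALSE
HK,2,AN,Acacia nilotica,native,FALSE
HK,2,DS,Dalbergia sissoo,native,FALSE
HK,3,LC,Lantana camara,invasive,TRUE
HK,3,DC,Diospyros cordifolia,native,FALSE
HK,3,ZN,Ziziphus nummularia,native,FALSE
HK,3,AI,Azadirachta indica,introduced,FALSE
HK,4,PC,Prosopis cineraria,native,TRUE
HK,4,CF,Cassia fistula,native,FALSE
HK,4,GRE,Grewia tenax,native,FALSE
HK,4,CD,Capparis decidua,native,FALSE
HK,4,MK,Murraya koenigii,native,FALSE
HK,4,DR,Drypetes roxburghii,native,FALSE
HK,5,PJ,Prosopis juliflora,invasive,TRUE
HK,5,BM,Bombax malabarica,native,FALSE
HK,5,MP,Milletia peguensis,native,FALSE
HK,5,AE,Ailanthus excelsa,native,FALSE
HK,5,TA,Terminalia arjuna,native,FALSE
JCF,1,PJ,Prosopis juliflora,invasive,TRUE
JCF,1,CS,Capparis sepiaria,native,FALSE
JCF,1,CAR,Carissa spinarum,native,FALSE
JCF,1,AI,Azadirachta indica,introduced,FALSE
JCF,2,HI,Holoptelea integrifolia,native,TRUE
JCF,2,PP,Pongamia pinnata,native,FALSE
JCF,2,AA,Albizia amara,native,FALSE
JCF,2,CF,Cassia fistula,native,FALSE
JCF,2,SS,Senna siamea,native,FALSE
JCF,2,TG,Tectona grandis,native,FALSE
JCF,2,PC,Prosopis cineraria,native,FALSE
JCF,3,LC,Lantana camara,invasive,TRUE
JCF,3,ZN,Ziziphus nummularia,native,FALSE
JCF,3,BM,Bombax malabarica,native,FALSE
MEH,1,LC,Lantana camara,invasive,TRUE
MEH,1,ADV,Adhatoda vasica,native,FALSE
MEH,1,AN,Acacia nilotica,native,FALSE
MEH,1,HI,Holoptelea integrifolia,native,FALSE
MEH,1,PP,Pongamia pinnata,native,FALSE
MEH,1,CF,Cassia fistula,native,FALSE
MEH,2,CT,Cassia tora,introduced,TRUE
MEH,2,ZN,Ziziphus nummularia,native,FALSE
MEH,2,AL,Acacia leucophloea,native,FALSE
MEH,2,GRE,Grewia tenax,native,FALSE
MEH,3,ABU,Abutilon,native,TRUE
MEH,3,CS,Capparis sepiaria,native,FALSE
MEH,3,CD,Capparis decidua,native,FALSE
MEH,4,AI,Azadirachta indica,introduced,TRUE
MEH,4,PJ,Prosopis juliflora,invasive,FALSE
JNU,1,BR,Balanites roxburghii,native,TRUE
JNU,1,LC,Lantana camara,invasive,FALSE
JNU,1,ZN,Ziziphus nummularia,native,FALSE
JNU,1,ZM,Ziziphus mauritiana,native,FALSE
JNU,2,CD,Capparis decidua,native,TRUE
JNU,2,ADV,Adhatoda vasica,native,FALSE
JNU,2,AI,Azadirachta indica,introduced,FALSE
JNU,2,AL,Acacia leucophloea,native,FALSE
JNU,3,PJ,Prosopis juliflora,invasive,TRUE
JNU,3,CS,Capparis sepiaria,native,FALSE
JNU,3,DC,Diospyros cordifolia,native,FALSE
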
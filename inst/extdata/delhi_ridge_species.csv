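code,scientific_name,status
LC,Lantana camara,invasive
PJ,Prosopis juliflora,invasive
LL,Leucaena leucocephala,invasive
OP,Opuntia,invasive
AI,Azadirachta indica,introduced
CT,Cassia tora,introduced
MOA,Morus alba,introduced
AA,Albizia amara,native
ABU,Abutilon,native
ADV,Adhatoda vasica,native
AE,Ailanthus excelsa,native
AL,Acacia leucophloea,native
AN,Acacia nilotica,native
AS,Acacia senegal,native
BM,Bombax malabarica,native
BR,Balanites roxburghii,native
BS,Bougainvillea spectabilis,native
CAR,Carissa spinarum,native
CD,Capparis decidua,native
CF,Cassia fistula,native
CS,Capparis sepiaria,native
DC,Diospyros cordifolia,native
DR,Drypetes roxburghii,native
DS,Dalbergia sissoo,native
EL,Ehretia laevis,native
GRE,Grewia tenax,native
HI,Holoptelea integrifolia,native
MK,Murraya koenigii,native
MP,Milletia peguensis,native
MS,Maytenus senegalensis,native
PC,Prosopis cineraria,native
PP,Pongamia pinnata,native
SS,Senna siamea,native
TA,Terminalia arjuna,native
TG,Tectona grandis,native
ZM,Ziziphus mauritiana,native
ZN,Ziziphus nummularia,native
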
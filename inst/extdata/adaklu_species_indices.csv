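family,species,local_name,voucher_id,conservation_status,ur,ci,fc,nu,rfc,ri,cve
Poaceae,Bambusa vulgaris,Pamploti,UHAS/ITAM/2023/L029,LC,440,1.705,162,4,0.628,0.823,0.714
Arecaceae,Borassus aethiopum,Agorti,UHAS/ITAM/2023/L030,LC,406,1.574,211,2,0.818,0.670,0.429
Arecaceae,Elaeis guineensis,Deti,UHAS/ITAM/2023/L001,LC,397,1.539,251,2,0.973,0.750,0.499
Fabaceae,Senna siamea,Zangarati,UHAS/ITAM/2023/L028,LC,288,1.116,107,3,0.415,0.588,0.231
Meliaceae,Azadirachta indica,Liliti,UHAS/ITAM/2023/L003,LC,265,1.027,103,3,0.399,0.580,0.205
Apocynaceae,Funtumia africana,Kpomi,UHAS/ITAM/2024/SB001,LC,199,0.771,138,2,0.535,0.525,0.138
Cactaceae,Rhipsalis baccifera,Adzorka,UHAS/ITAM/2024/L001,LC,187,0.725,187,1,0.725,0.498,0.088
Arecaceae,Raphia palma-pinus,Ebe,UHAS/ITAM/2024/L002,NT,175,0.678,175,1,0.678,0.474,0.077
Moraceae,Antiaris toxicaria,Logo,UHAS/ITAM/2024/SB002,LC,163,0.632,163,1,0.632,0.450,0.067
Phyllanthaceae,Bridelia ferruginea,Akamiti,UHAS/ITAM/2023/SB001,LC,137,0.531,137,1,0.531,0.398,0.047
Fabaceae,Baphia nitida,Toti,UHAS/ITAM/2024/L003,LC,130,0.504,130,1,0.504,0.384,0.042
Apocynaceae,Cryptolepis nigrescens,Globo,UHAS/ITAM/2024/L008,NE,127,0.492,127,1,0.492,0.378,0.040
Poaceae,Andropogon gayanus,,UHAS/ITAM/2024/L009,NE,124,0.481,124,1,0.481,0.372,0.038
Musaceae,Musa x sapientum,Toworka,UHAS/ITAM/2023/L009,LC,121,0.469,121,1,0.469,0.366,0.037
Combretaceae,Anogeissus leiocarpa,Hehe/Hihe,UHAS/ITAM/2024/L004,LC,110,0.426,110,1,0.426,0.344,0.030
Rubiaceae,Gardenia ternifolia,Efeti,UHAS/ITAM/2024/L005,LC,101,0.391,101,1,0.391,0.326,0.026
Fabaceae,Leucaena leucocephala,Klikagbe,UHAS/ITAM/2024/L006,NE,91,0.353,91,1,0.353,0.306,0.021
Arecaceae,Eremospatha macrocarpa,Mfia/cane,UHAS/ITAM/2024/L007,LC,83,0.322,83,1,0.322,0.290,0.017
Acanthaceae,Avicennia germinans,Amuti/Amutsi,UHAS/ITAM/2024/L010,LC,81,0.314,81,1,0.314,0.286,0.016
Cyperaceae,Cyperus papyrus,Keti,UHAS/ITAM/2024/AP001,LC,79,0.306,79,1,0.306,0.282,0.016
Lamiaceae,Tectona grandis,Teak,UHAS/ITAM/2024/L011,EN,74,0.287,74,1,0.287,0.272,0.014
Arecaceae,Cocos nucifera,Neti,UHAS/ITAM/2021/FR008,NE,73,0.283,73,1,0.283,0.270,0.013
Fabaceae,Tamarindus indica,Eforti,UHAS/ITAM/2024/FR001,LC,68,0.264,68,1,0.264,0.260,0.012
Ebenaceae,Diospyros mespiliformis,Keyi/Keke,UHAS/ITAM/2024/L012,LC,67,0.260,67,1,0.260,0.258,0.011
Arecaceae,Raphia hookeri,Alati,UHAS/ITAM/2024/L013,LC,62,0.240,62,1,0.240,0.249,0.010
Typhaceae,Typha domingensis,Ava,UHAS/ITAM/2024/L014,LC,61,0.236,61,1,0.236,0.247,0.009
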
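use_category,species,fl
main pole,Azadirachta indica,100.00
main pole,Anogeissus leiocarpa,100.00
main pole,Avicennia germinans,100.00
main pole,Baphia nitida,100.00
main pole,Gardenia ternifolia,100.00
main pole,Diospyros mespiliformis,100.00
main pole,Tamarindus indica,100.00
main pole,Tectona grandis,100.00
main pole,Bridelia ferruginea,100.00
main pole,Antiaris toxicaria,100.00
main pole,Senna siamea,82.24
main pole,Funtumia africana,44.20
main beam,Borassus aethiopum,100.00
main beam,Funtumia africana,100.00
main beam,Leucaena leucocephala,100.00
main beam,Senna siamea,100.00
main beam,Azadirachta indica,70.87
main beam,Bambusa vulgaris,67.90
wall lath,Elaeis guineensis,100.00
wall lath,Bambusa vulgaris,54.32
roof lath,Bambusa vulgaris,100.00
roof lath,Borassus aethiopum,92.42
roof lath,Senna siamea,86.92
roof lath,Azadirachta indica,86.41
binding material,Musa x sapientum,100.00
binding material,Cryptolepis nigrescens,100.00
binding material,Rhipsalis baccifera,100.00
binding material,Eremospatha macrocarpa,100.00
thatch material,Raphia hookeri,100.00
thatch material,Raphia palma-pinus,100.00
thatch material,Cyperus papyrus,100.00
thatch material,Cocos nucifera,100.00
thatch material,Typha domingensis,100.00
thatch material,Andropogon gayanus,100.00
thatch material,Elaeis guineensis,58.17
thatch material,Bambusa vulgaris,49.38
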
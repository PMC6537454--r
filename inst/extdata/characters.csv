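leaf,character,state
nan,mating_position,tilted_right
aca,mating_position,symmetric
pac,mating_position,upright_right
mac,mating_position,symmetric
bro,mating_position,symmetric
moj,mating_position,symmetric
buz,mating_position,symmetric
nan,phallus,symmetric
aca,phallus,acanthoptera_type_asym
pac,phallus,pachea_type_asym
mac,phallus,symmetric
bro,phallus,symmetric
moj,phallus,symmetric
buz,phallus,symmetric
nan,epandrial_lobes,symmetric
aca,epandrial_lobes,symmetric
pac,epandrial_lobes,asymmetric
mac,epandrial_lobes,symmetric
bro,epandrial_lobes,nd
moj,epandrial_lobes,nd
buz,epandrial_lobes,nd
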
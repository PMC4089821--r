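xread 'Ectateus and Selinus with outgroups: 20 taxa x 40 unordered morphological characters (states 0/1/2, ? = missing)' 40 20
Zidalus_latipes                00000 00000 01000 10000 00000 00100 00000 00000
Lechius_abacoides              00000 10000 01000 00000 00000 00000 00000 00000
Pseudoselinus_punctatostriatus 00000 01000 01000 00101 00000 01100 00000 00000
Upembarus_upembaensis          00000 01000 01000 00100 00000 00100 00000 00000
Ectateus_crenatus              00111 00110 10211 10011 11100 00001 00100 10001
Ectateus_curtulus              0?010 00100 10211 00011 10100 00??? ????? ??000
Ectateus_ghesquierei           00111 00110 10211 00011 11100 00001 00100 10001
Ectateus_laevistriatus         01001 10000 00101 10001 00000 10110 01011 01100
Ectateus_lamottei              01001 10000 00101 00001 00000 10110 01011 01100
Ectateus_modestus              01111 00110 10211 10011 10100 00001 00100 10000
Ectateus_ursynowiensis         10000 00000 00100 01000 00101 00001 00100 00000
Ectateus_villiersi             10000 00001 00100 01000 00001 00001 00100 00000
Selinus_calcaripes             01111 00110 10211 10011 10000 00001 00100 10000
Selinus_convexipennis          01001 10000 00101 00001 00000 10110 01010 01100
Selinus_gravis                 01000 10000 00100 00001 00000 10110 01010 01100
Selinus_malaisei               01000 10000 00100 00000 00010 10110 11010 02100
Selinus_medius                 01000 10000 00100 00000 00010 10110 11010 02100
Selinus_planus                 01000 10001 00100 00001 00000 01100 00010 00010
Selinus_plicicollis            01000 10000 00100 00000 00010 10110 11010 02100
Selinus_striatus               01000 10001 00100 00001 00000 01100 00010 00010
;
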